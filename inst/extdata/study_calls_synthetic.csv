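lab_id,chemical_code,run,call_vrm,call_epi2sensa
Mattek,C01,1,sensitizer,sensitizer
Mattek,C01,2,sensitizer,sensitizer
Mattek,C01,3,sensitizer,sensitizer
Mattek,C02,1,sensitizer,sensitizer
Mattek,C02,2,non_sensitizer,sensitizer
Mattek,C02,3,sensitizer,sensitizer
Mattek,C03,1,sensitizer,sensitizer
Mattek,C03,2,sensitizer,sensitizer
Mattek,C03,3,sensitizer,sensitizer
Mattek,C04,1,sensitizer,sensitizer
Mattek,C05,1,non_sensitizer,non_sensitizer
Mattek,C05,2,non_sensitizer,non_sensitizer
Mattek,C05,3,non_sensitizer,non_sensitizer
Mattek,C06,1,sensitizer,sensitizer
Mattek,C07,1,sensitizer,sensitizer
Mattek,C07,2,sensitizer,sensitizer
Mattek,C07,3,sensitizer,sensitizer
Mattek,C08,1,sensitizer,sensitizer
Mattek,C09,1,sensitizer,sensitizer
Mattek,C09,2,sensitizer,sensitizer
Mattek,C09,3,sensitizer,sensitizer
Mattek,C10,1,sensitizer,sensitizer
Mattek,C11,1,sensitizer,sensitizer
Mattek,C11,2,sensitizer,sensitizer
Mattek,C11,3,sensitizer,sensitizer
Mattek,C12,1,sensitizer,sensitizer
Mattek,C12,2,sensitizer,sensitizer
Mattek,C12,3,non_sensitizer,non_sensitizer
Mattek,C13,1,sensitizer,sensitizer
Mattek,C14,1,sensitizer,sensitizer
Mattek,C14,2,sensitizer,sensitizer
Mattek,C14,3,sensitizer,sensitizer
Mattek,C15,1,non_sensitizer,non_sensitizer
Mattek,C15,2,non_sensitizer,non_sensitizer
Mattek,C15,3,non_sensitizer,non_sensitizer
Mattek,C16,1,non_sensitizer,non_sensitizer
Mattek,C16,2,non_sensitizer,non_sensitizer
Mattek,C16,3,sensitizer,non_sensitizer
Mattek,C17,1,non_sensitizer,non_sensitizer
Mattek,C18,1,sensitizer,non_sensitizer
Mattek,C18,2,sensitizer,non_sensitizer
Mattek,C18,3,non_sensitizer,non_sensitizer
Mattek,C19,1,non_sensitizer,non_sensitizer
Mattek,C20,1,sensitizer,non_sensitizer
Eurofins,C01,1,sensitizer,sensitizer
Eurofins,C01,2,sensitizer,sensitizer
Eurofins,C01,3,sensitizer,sensitizer
Eurofins,C02,1,sensitizer,sensitizer
Eurofins,C02,2,sensitizer,sensitizer
Eurofins,C02,3,sensitizer,sensitizer
Eurofins,C03,1,sensitizer,sensitizer
Eurofins,C03,2,sensitizer,sensitizer
Eurofins,C03,3,sensitizer,sensitizer
Eurofins,C04,1,sensitizer,sensitizer
Eurofins,C05,1,non_sensitizer,non_sensitizer
Eurofins,C05,2,sensitizer,non_sensitizer
Eurofins,C05,3,non_sensitizer,non_sensitizer
Eurofins,C06,1,sensitizer,sensitizer
Eurofins,C07,1,sensitizer,sensitizer
Eurofins,C07,2,sensitizer,sensitizer
Eurofins,C07,3,sensitizer,sensitizer
Eurofins,C08,1,sensitizer,sensitizer
Eurofins,C09,1,sensitizer,sensitizer
Eurofins,C09,2,sensitizer,sensitizer
Eurofins,C09,3,sensitizer,sensitizer
Eurofins,C10,1,sensitizer,sensitizer
Eurofins,C11,1,sensitizer,sensitizer
Eurofins,C11,2,sensitizer,sensitizer
Eurofins,C11,3,sensitizer,sensitizer
Eurofins,C12,1,non_sensitizer,non_sensitizer
Eurofins,C12,2,non_sensitizer,non_sensitizer
Eurofins,C12,3,sensitizer,sensitizer
Eurofins,C13,1,sensitizer,sensitizer
Eurofins,C14,1,sensitizer,non_sensitizer
Eurofins,C14,2,non_sensitizer,sensitizer
Eurofins,C14,3,sensitizer,non_sensitizer
Eurofins,C15,1,non_sensitizer,non_sensitizer
Eurofins,C15,2,non_sensitizer,non_sensitizer
Eurofins,C15,3,sensitizer,non_sensitizer
Eurofins,C16,1,non_sensitizer,non_sensitizer
Eurofins,C16,2,non_sensitizer,non_sensitizer
Eurofins,C16,3,non_sensitizer,non_sensitizer
Eurofins,C17,1,non_sensitizer,non_sensitizer
Eurofins,C18,1,sensitizer,non_sensitizer
Eurofins,C18,2,non_sensitizer,non_sensitizer
Eurofins,C18,3,sensitizer,non_sensitizer
Eurofins,C19,1,non_sensitizer,non_sensitizer
Eurofins,C20,1,non_sensitizer,sensitizer
BRT,C01,1,sensitizer,sensitizer
BRT,C01,2,sensitizer,sensitizer
BRT,C01,3,sensitizer,sensitizer
BRT,C02,1,sensitizer,sensitizer
BRT,C02,2,sensitizer,sensitizer
BRT,C02,3,sensitizer,sensitizer
BRT,C03,1,non_sensitizer,sensitizer
BRT,C03,2,sensitizer,sensitizer
BRT,C03,3,sensitizer,sensitizer
BRT,C04,1,sensitizer,sensitizer
BRT,C05,1,non_sensitizer,non_sensitizer
BRT,C05,2,non_sensitizer,non_sensitizer
BRT,C05,3,non_sensitizer,non_sensitizer
BRT,C06,1,sensitizer,sensitizer
BRT,C07,1,sensitizer,sensitizer
BRT,C07,2,sensitizer,sensitizer
BRT,C07,3,sensitizer,sensitizer
BRT,C08,1,sensitizer,sensitizer
BRT,C09,1,sensitizer,sensitizer
BRT,C09,2,sensitizer,sensitizer
BRT,C09,3,sensitizer,sensitizer
BRT,C10,1,sensitizer,sensitizer
BRT,C11,1,sensitizer,sensitizer
BRT,C11,2,sensitizer,sensitizer
BRT,C11,3,non_sensitizer,non_sensitizer
BRT,C12,1,sensitizer,sensitizer
BRT,C12,2,non_sensitizer,non_sensitizer
BRT,C12,3,sensitizer,sensitizer
BRT,C13,1,sensitizer,sensitizer
BRT,C14,1,sensitizer,sensitizer
BRT,C14,2,sensitizer,sensitizer
BRT,C14,3,sensitizer,sensitizer
BRT,C15,1,sensitizer,non_sensitizer
BRT,C15,2,sensitizer,sensitizer
BRT,C15,3,non_sensitizer,non_sensitizer
BRT,C16,1,non_sensitizer,non_sensitizer
BRT,C16,2,non_sensitizer,non_sensitizer
BRT,C16,3,non_sensitizer,non_sensitizer
BRT,C17,1,non_sensitizer,non_sensitizer
BRT,C18,1,sensitizer,non_sensitizer
BRT,C18,2,sensitizer,non_sensitizer
BRT,C18,3,sensitizer,non_sensitizer
BRT,C19,1,non_sensitizer,non_sensitizer
BRT,C20,1,sensitizer,sensitizer
FDSC,C04,1,sensitizer,sensitizer
FDSC,C06,1,sensitizer,sensitizer
FDSC,C08,1,non_sensitizer,sensitizer
FDSC,C10,1,sensitizer,sensitizer
FDSC,C13,1,non_sensitizer,sensitizer
FDSC,C17,1,sensitizer,non_sensitizer
FDSC,C19,1,non_sensitizer,non_sensitizer
FDSC,C20,1,sensitizer,sensitizer
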