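code,name,cas,logp,pre_pro_hapten,in_vivo_class,ghs_subcat,vehicle,vrm_call,epi2sensa_call
C01,"2,4-Dinitrochlorobenzene",97-00-7,2.17,FALSE,sensitizer,1A,AOO,positive,positive
C02,p-Phenylenediamine,106-50-3,-0.3,TRUE,sensitizer,1A,AOO,positive,positive
C03,Metol,55-55-0,0.63,TRUE,sensitizer,1A,DW,positive,positive
C04,Tetrachlorosalicylanilide,1154-59-2,5.87,FALSE,sensitizer,1A,AOO,positive,positive
C05,Lauryl gallate,1166-52-5,6.9,TRUE,sensitizer,1A,AOO,negative,negative
C06,Methyl heptine carbonate,111-12-6,2.79,FALSE,sensitizer,1A,AOO,positive,positive
C07,Isoeugenol,97-54-1,3.04,TRUE,sensitizer,1B,AOO,positive,positive
C08,Glyoxal (40% solution in water),107-22-2,-0.08,FALSE,sensitizer,1A,DW,positive,positive
C09,Abietic acid,514-10-3,3.92,TRUE,sensitizer,1B,AOO,positive,positive
C10,Dibutyl aniline,613-29-6,4.7,TRUE,sensitizer,1B,AOO,positive,positive
C11,Amyl cinnamic aldehyde,122-40-7,3.99,FALSE,sensitizer,1B,AOO,positive,positive
C12,Benzisothiazolinone,2634-33-5,0.8,FALSE,sensitizer,1B,AOO,positive,positive
C13,Imidazolidinyl urea,39236-46-9,-0.86,FALSE,sensitizer,1B,DW,positive,positive
C14,Farnesol,4602-84-0,4.91,FALSE,sensitizer,1B,AOO,positive,positive
C15,Cetrimide,57-09-0,3.18,FALSE,non_sensitizer,not_classified,EtOH50,negative,negative
C16,Lactic acid,50-21-5,-0.72,FALSE,non_sensitizer,not_classified,DW,negative,negative
C17,Benzyl butyl phthalate,85-68-7,4.84,FALSE,non_sensitizer,not_classified,AOO,negative,negative
C18,Diethyl phthalate,84-66-2,2.44,FALSE,non_sensitizer,not_classified,AOO,positive,negative
C19,Hexane,110-54-3,3.9,FALSE,non_sensitizer,not_classified,AOO,negative,negative
C20,1-Iodohexane,638-45-9,3.99,FALSE,non_sensitizer,not_classified,AOO,positive,positive
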