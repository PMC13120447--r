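# Record IO, reference panel, vehicle selection.

test_that("tissue records survive a write/read round trip, wide and long Ct", {
  rec <- make_run(doses = c(12.5, 6.25), viability = c(70, 95),
                  folds = fold_matrix(c(20, 3, 3, 6), c(4, 1.5, 1.5, 2)))
  wide <- withr::local_tempfile(fileext = ".csv")
  write_tissue_records(rec, wide)
  back <- read_tissue_records(wide)
  expect_equal(as.data.frame(back), as.data.frame(rec), tolerance = 1e-12)

  main <- withr::local_tempfile(fileext = ".csv")
  ctf <- withr::local_tempfile(fileext = ".csv")
  write_tissue_records(rec, main, ct_path = ctf)
  back2 <- read_tissue_records(main, ct_path = ctf)
  expect_equal(as.data.frame(back2), as.data.frame(rec), tolerance = 1e-12)
})

test_that("role and vehicle tokens are normalized case-insensitively", {
  rec <- make_run()
  path <- withr::local_tempfile(fileext = ".csv")
  out <- as.data.frame(rec)
  out$role[out$role == "killed"] <- "Killed"
  out$role[out$role == "pc_clotrimazole"] <- "CLOTRIMAZOLE"
  out$vehicle <- "aoo"
  utils::write.csv(out, path, row.names = FALSE, na = "")
  back <- read_tissue_records(path)
  expect_identical(sort(unique(back$role)), sort(unique(rec$role)))
  expect_true(all(back$vehicle == "AOO"))
})

test_that("malformed inputs are rejected with row-numbered diagnostics", {
  rec <- make_run()
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- as.data.frame(rec)
  bad$abs_490[3] <- NA
  utils::write.csv(bad, path, row.names = FALSE, na = "NA")
  expect_error(read_tissue_records(path), "abs_490.*row.*4")

  bad <- as.data.frame(rec)
  bad$role[2] <- "mystery"
  utils::write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(read_tissue_records(path), "role.*'mystery'.*row.* 3")

  bad <- as.data.frame(rec)[-(1:3)]  # drop lab_id, run_id, tissue_id
  utils::write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(read_tissue_records(path), "missing mandatory column")

  bad <- as.data.frame(rec)
  bad$tissue_id[2] <- bad$tissue_id[1]
  utils::write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(read_tissue_records(path), "duplicate \\(run_id, tissue_id\\)")
})

test_that("killed tissues may not carry Ct values and test tissues need a dose", {
  rec <- as.data.frame(make_run())
  rec$ct_GAPDH[rec$role == "killed"][1] <- 18
  expect_error(validate_tissue_records(rec), "killed-control.*Ct")

  rec <- as.data.frame(make_run())
  rec$concentration[rec$role == "test"] <- 0
  expect_error(validate_tissue_records(rec), "non-positive concentration")
})

test_that("the packaged reference panel has the documented composition", {
  panel <- load_reference_panel()
  expect_identical(nrow(panel), 20L)
  expect_identical(sum(panel$in_vivo_class == "sensitizer"), 14L)
  expect_identical(sum(panel$in_vivo_class == "non_sensitizer"), 6L)
  expect_identical(sum(panel$pre_pro_hapten), 6L)
  expect_identical(sum(panel$logp >= 3.5), 9L)
  expect_setequal(panel$ghs_subcat[panel$in_vivo_class == "sensitizer"],
                  c("1A", "1B"))
})

test_that("panel cells agree with an independently transcribed copy", {
  # second transcription, typed separately from the shipped fixture
  second <- data.frame(
    name = c("2,4-Dinitrochlorobenzene", "Lauryl gallate", "Isoeugenol",
             "Cetrimide", "Diethyl phthalate", "1-Iodohexane",
             "Benzisothiazolinone", "Lactic acid"),
    cas = c("97-00-7", "1166-52-5", "97-54-1", "57-09-0", "84-66-2",
            "638-45-9", "2634-33-5", "50-21-5"),
    logp = c(2.17, 6.9, 3.04, 3.18, 2.44, 3.99, 0.8, -0.72),
    ghs_subcat = c("1A", "1A", "1B", "not_classified", "not_classified",
                   "not_classified", "1B", "not_classified"),
    vrm_call = c("positive", "negative", "positive", "negative",
                 "positive", "positive", "positive", "negative"),
    epi2sensa_call = c("positive", "negative", "positive", "negative",
                       "negative", "positive", "positive", "negative"),
    stringsAsFactors = FALSE)
  panel <- load_reference_panel()
  got <- panel[match(second$name, panel$name), names(second)]
  rownames(got) <- NULL
  expect_equal(got, second)
})

test_that("vehicle selection follows solubility then preference order", {
  grid <- function(aoo_max, dw_max, etoh_max) {
    sol <- expand.grid(vehicle = c("AOO", "DW", "EtOH50"),
                       concentration = dilution_series(),
                       stringsAsFactors = FALSE)
    lim <- c(AOO = aoo_max, DW = dw_max, EtOH50 = etoh_max)
    sol$soluble <- sol$concentration <= lim[sol$vehicle]
    sol
  }
  # soluble everywhere at the top: first preference wins
  expect_equal(select_vehicle(grid(50, 50, 50)),
               list(vehicle = "AOO", concentration = 50))
  # highest soluble concentration wins
  expect_equal(select_vehicle(grid(0.78125, 12.5, 6.25)),
               list(vehicle = "DW", concentration = 12.5))
  # tie broken by preference order
  expect_equal(select_vehicle(grid(3.125, 3.125, -1)),
               list(vehicle = "AOO", concentration = 3.125))
  expect_error(select_vehicle(grid(-1, -1, -1)), "insoluble")
})

test_that("vehicle selection is invariant to entry order and matches an
           enumeration oracle", {
  oracle <- function(sol) {
    # try every (vehicle, conc) pair sorted by conc desc then preference
    ok <- sol[as.logical(sol$soluble), ]
    pref <- match(ok$vehicle, c("AOO", "DW", "EtOH50"))
    ok <- ok[order(-ok$concentration, pref), ]
    list(vehicle = ok$vehicle[1], concentration = ok$concentration[1])
  }
  set.seed(404)
  for (i in 1:25) {
    sol <- expand.grid(vehicle = c("AOO", "DW", "EtOH50"),
                       concentration = sample(dilution_series(), 6),
                       stringsAsFactors = FALSE)
    sol$soluble <- runif(nrow(sol)) < 0.4
    if (!any(sol$soluble)) next
    got <- select_vehicle(sol)
    expect_equal(got, oracle(sol))
    perm <- sol[sample(nrow(sol)), ]
    expect_equal(select_vehicle(perm), got)
  }
})

test_that("the dilution grid is the 13-level 2-fold series from 50%", {
  s <- dilution_series()
  expect_length(s, 13)
  expect_equal(s[1], 50)
  expect_equal(s[-1] / s[-13], rep(0.5, 12))
  expect_equal(round(s[13], 4), 0.0122)
})

test_that("criteria config files select presets and apply overrides", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("criteria: VRM"), path)
  expect_identical(read_criteria_config(path)$min_active_genes, 1L)

  writeLines(c("criteria: Epi2SensA",
               "overrides:",
               "  viability_threshold_pct: 70",
               "  min_active_genes: 1"), path)
  cs <- read_criteria_config(path)
  expect_identical(cs$viability_threshold_pct, 70L)
  expect_identical(cs$min_active_genes, 1L)

  writeLines(c("criteria: Epi2SensA", "overrides:", "  nonsense: 3"), path)
  expect_error(read_criteria_config(path), "unknown override")
})
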