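make_ct <- function(target_shift) {
  # one target gene, reference fixed at 12 cycles; target Ct = 24 in the
  # control and 24 + target_shift under treatment, 3 bio x 2 tech
  grid <- expand.grid(gene = c("16S", "nidA"),
                      condition = c("glucose", "pyrene"),
                      bio_rep = 1:3, tech_rep = 1:2,
                      stringsAsFactors = FALSE)
  grid$ct <- ifelse(grid$gene == "16S", 12,
                    ifelse(grid$condition == "glucose", 24,
                           24 + target_shift))
  grid
}

test_that("ddCt identities: unit fold at no shift, 2.0 at ddCt = -1", {
  rel0 <- delta_delta_ct(make_ct(0), "16S", "glucose")
  expect_equal(rel0$fold_change, rep(1.0, nrow(rel0)))
  rel <- delta_delta_ct(make_ct(-1), "16S", "glucose")
  up <- rel[rel$gene == "nidA" & rel$condition == "pyrene", ]
  expect_equal(up$fold_change, 2.0)
  expect_equal(up$log2_fold_change, 1.0)
  expect_equal(up$n_bio, 3L)
})

test_that("reference gene folds are exactly 1 and Ct shifts cancel", {
  set.seed(10)
  tab <- simulate_ct_table(c(nidA = 4, phtA = 0.5, gyrB = 1),
                           conditions = c("pyrene", "DIPA"),
                           control_condition = "glucose",
                           ct_noise = 0.3, seed = 6)
  rel <- delta_delta_ct(tab, "16S", "glucose")
  ref <- rel[rel$gene == "16S", ]
  expect_identical(ref$fold_change, rep(1.0, nrow(ref)))
  # normalization invariance: add a constant Ct per (condition, bio_rep)
  shifted <- tab
  key <- paste(tab$condition, tab$bio_rep)
  offs <- setNames(seq_along(unique(key)) * 1.7, unique(key))
  shifted$ct <- shifted$ct + offs[key]
  rel_s <- delta_delta_ct(shifted, "16S", "glucose")
  expect_equal(rel_s$fold_change, rel$fold_change, tolerance = 1e-12)
})

test_that("a constructed 3-gene table matches a by-hand spreadsheet evaluation", {
  set.seed(3)
  grid <- expand.grid(gene = c("ref", "gA", "gB"),
                      condition = c("ctl", "trt"),
                      bio_rep = 1:3, tech_rep = 1:3,
                      stringsAsFactors = FALSE)
  grid$ct <- round(runif(nrow(grid), 10, 30), 2)
  rel <- delta_delta_ct(grid, "ref", "ctl")
  # independent cell-by-cell evaluation of the Livak formula
  for (g in c("gA", "gB")) for (cond in c("ctl", "trt")) {
    dct <- sapply(1:3, function(b) {
      mean(grid$ct[grid$gene == g & grid$condition == cond &
                     grid$bio_rep == b]) -
        mean(grid$ct[grid$gene == "ref" & grid$condition == cond &
                       grid$bio_rep == b])
    })
    dct_ctl <- sapply(1:3, function(b) {
      mean(grid$ct[grid$gene == g & grid$condition == "ctl" &
                     grid$bio_rep == b]) -
        mean(grid$ct[grid$gene == "ref" & grid$condition == "ctl" &
                       grid$bio_rep == b])
    })
    expected <- mean(2^(-(dct - mean(dct_ctl))))
    got <- rel$fold_change[rel$gene == g & rel$condition == cond]
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("missing strata produce named errors", {
  tab <- make_ct(0)
  expect_error(delta_delta_ct(tab, "16S", "acetate"), "control condition")
  noref <- tab[!(tab$gene == "16S" & tab$condition == "pyrene" &
                   tab$bio_rep == 2), ]
  expect_error(delta_delta_ct(noref, "16S", "glucose"), "pyrene, 2")
  expect_error(delta_delta_ct(tab[, -5], "16S", "glucose"), "missing column")
})

test_that("twofold expression calls detect a true 4-fold induction reliably", {
  rel <- delta_delta_ct(make_ct(-1.4), "16S", "glucose")
  expect_true(expression_call(rel)$called[rel$gene == "nidA" &
                                            rel$condition == "pyrene"])
  expect_false(any(expression_call(rel)$called[rel$gene == "16S"]))
  hits <- vapply(1:100, function(s) {
    tab <- simulate_ct_table(c(nidA = 4), conditions = "pyrene",
                             control_condition = "glucose",
                             ct_noise = 0.2, seed = s)
    rel <- delta_delta_ct(tab, "16S", "glucose")
    called <- expression_call(rel)$called
    called[rel$gene == "nidA" & rel$condition == "pyrene"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("simulated Ct tables round-trip their generating fold changes", {
  tab1 <- simulate_ct_table(c(gA = 1, gB = 1), conditions = "trt",
                            control_condition = "ctl", ct_noise = 0, seed = 1)
  rel1 <- delta_delta_ct(tab1, "16S", "ctl")
  expect_equal(rel1$fold_change, rep(1.0, nrow(rel1)))
  tab2 <- simulate_ct_table(c(gA = 2), conditions = "trt",
                            control_condition = "ctl", ct_noise = 0, seed = 1)
  rel2 <- delta_delta_ct(tab2, "16S", "ctl")
  expect_equal(rel2$fold_change[rel2$gene == "gA" & rel2$condition == "trt"],
               2.0)
  # stochastic recovery of a fold map across seeds
  folds <- c(gA = 4, gB = 0.5, gC = 1)
  rec <- sapply(1:50, function(s) {
    tab <- simulate_ct_table(folds, conditions = "trt",
                             control_condition = "ctl", ct_noise = 0.2,
                             seed = 100 + s)
    rel <- delta_delta_ct(tab, "16S", "ctl")
    rel$fold_change[rel$condition == "trt" & rel$gene %in% names(folds)]
  })
  genes_in_order <- sort(names(folds))
  mean_rec <- rowMeans(rec)
  expect_true(all(abs(mean_rec / folds[genes_in_order] - 1) < 0.15))
  # seed determinism
  expect_identical(
    simulate_ct_table(folds, ct_noise = 0.3, seed = 9),
    simulate_ct_table(folds, ct_noise = 0.3, seed = 9)
  )
  expect_error(simulate_ct_table(c(gA = -1)), "> 0")
})
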