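# small synthetic isotopologue fixtures, built in code
fix_table <- function() {
  data.frame(
    metabolite = rep(c("LAC", "CIT"), c(4, 7)),
    pathway = rep(c("glycolysis", "TCA"), c(4, 7)),
    condition = "ctl",
    tracer = "U13C6",
    mass_shift = c(0:3, 0:6),
    amount = c(25, 0, 0, 75, 40, 0, 6, 0, 0, 0, 4))
}

test_that("calibration-curve quantitation inverts the line with a floor", {
  line <- list(slope = 2, intercept = 0)
  expect_equal(quantify_from_calibration(10, line), 5)
  line2 <- list(slope = 1.5, intercept = 3)
  expect_equal(quantify_from_calibration(3, line2), 0)     # area == intercept
  expect_equal(quantify_from_calibration(1, line2), 0)     # below intercept
  expect_error(quantify_from_calibration(5, list(slope = 0, intercept = 1)),
               "invalid calibration")
})

test_that("labeling fractions normalize to the simplex", {
  tab <- fix_table()
  f <- labeling_fractions(tab, "LAC", "ctl")
  expect_equal(unname(f), c(0.25, 0, 0, 0.75))
  expect_equal(sum(f), 1)
  # invariance under positive rescaling of amounts
  tab2 <- tab; tab2$amount <- tab2$amount * 7.3
  expect_equal(labeling_fractions(tab2, "LAC", "ctl"), f)
  only0 <- tab[tab$mass_shift == 0 & tab$metabolite == "CIT", ]
  expect_equal(unname(labeling_fractions(only0, "CIT", "ctl")), 1)
  zero <- tab; zero$amount <- 0
  expect_error(labeling_fractions(zero, "LAC", "ctl"), "undefined fractions")
  expect_equal(labeling_rate(tab, "LAC", "ctl"), 0.75)
})

test_that("natural-isotope correction subtracts with a zero floor", {
  expect_equal(natural_isotope_correct(10, 3), 7)
  expect_equal(natural_isotope_correct(2, 5), 0)
  expect_equal(natural_isotope_correct(4.2, 0), 4.2)
  expect_equal(natural_isotope_correct(c(10, 2), c(3, 5)), c(7, 0))
  expect_error(natural_isotope_correct(-1, 0), ">= 0")
  # idempotent once the floor was hit
  once <- natural_isotope_correct(2, 5)
  expect_equal(natural_isotope_correct(once, 5), once)
  # never negative, for any inputs
  set.seed(2)
  a <- runif(50, 0, 10); b <- runif(50, 0, 10)
  expect_true(all(natural_isotope_correct(a, b) >= 0))
})

test_that("table-level correction matches the matched control rows", {
  lab <- fix_table()
  ctl <- lab; ctl$tracer <- "U12C6"
  ctl$amount <- c(95, 1, 0.5, 2, 44, 1, 8, 0.2, 0, 0, 1)
  both <- rbind(lab, ctl)
  corr <- correct_table_natural(both)
  expect_equal(corr$amount[corr$metabolite == "LAC"], c(25, 0, 0, 73))
  # CIT M+2: 6 - 8 floored at zero
  expect_equal(corr$amount[corr$metabolite == "CIT" & corr$mass_shift == 2], 0)
  expect_error(correct_table_natural(lab), "control")
  # selective mode touches only the flagged isotopologues
  flags <- data.frame(metabolite = "CIT", mass_shift = 2, condition = "ctl")
  sel <- correct_table_natural(both, flags)
  expect_equal(sel$amount[sel$metabolite == "LAC"],
               lab$amount[lab$metabolite == "LAC"])
  expect_equal(sel$amount[sel$metabolite == "CIT" & sel$mass_shift == 2], 0)
})

test_that("high natural-isotope isotopologues are flagged at 5%", {
  lab <- fix_table()
  ctl <- lab; ctl$tracer <- "U12C6"
  # citrate M+2 control is 8 against 6 labeled -> far above 5%
  ctl$amount <- c(0, 0, 0, 2, 0, 0, 8, 0, 0, 0, 0)
  both <- rbind(lab, ctl)
  flags <- flag_high_natural_isotope(both)
  expect_true(any(flags$metabolite == "CIT" & flags$mass_shift == 2))
  # LAC M+3: control 2 vs labeled 75 -> 2.7%, not flagged
  expect_false(any(flags$metabolite == "LAC"))
  # a zero control is never flagged
  ctl0 <- lab; ctl0$tracer <- "U12C6"; ctl0$amount <- 0
  expect_equal(nrow(flag_high_natural_isotope(rbind(lab, ctl0))), 0L)
  expect_error(flag_high_natural_isotope(lab), "control")
})

test_that("pathway totals sum labeled amounts over member metabolites", {
  tab <- fix_table()
  expect_equal(pathway_total_labeled(tab, "glycolysis", "ctl"), 75)
  expect_equal(pathway_total_labeled(tab, "TCA", "ctl"), 10)
  all0 <- tab; all0$amount[all0$mass_shift >= 1] <- 0
  expect_equal(pathway_total_labeled(all0, "TCA", "ctl"), 0)
  expect_error(pathway_total_labeled(tab, "urea_cycle", "ctl"),
               "unknown pathway")
})

test_that("pathway totals equal an exhaustive-sum oracle on random fixtures", {
  set.seed(33)
  for (rep in 1:5) {
    mets <- paste0("m", 1:8)
    pw <- sample(c("glycolysis", "TCA", "PPP", "NAS"), 8, replace = TRUE)
    rows <- do.call(rbind, lapply(1:8, function(i) {
      C <- sample(2:6, 1)
      data.frame(metabolite = mets[i], pathway = pw[i], condition = "x",
                 tracer = "U13C6", mass_shift = 0:C,
                 amount = round(runif(C + 1, 0, 20), 3))
    }))
    for (p in unique(pw)) {
      oracle <- 0
      for (i in which(pw == p))                # brute-force double loop
        for (j in seq_len(nrow(rows)))
          if (rows$metabolite[j] == mets[i] && rows$mass_shift[j] >= 1)
            oracle <- oracle + rows$amount[j]
      expect_equal(pathway_total_labeled(rows, p, "x"), oracle)
    }
    # additivity over the disjoint pathway partition
    expect_equal(sum(vapply(unique(pw), function(p)
      pathway_total_labeled(rows, p, "x"), 0)),
      sum(rows$amount[rows$mass_shift >= 1]))
  }
})

test_that("the heatmap transform adds a pseudo-count of 1", {
  tab <- fix_table()
  tab$amount[tab$metabolite == "CIT"] <- c(10, 0, 0, 0, 0, 0, 0)  # unlabeled
  full <- tab
  full$amount[full$metabolite == "LAC"] <- c(0, 0, 0, 50)         # labeled
  hm <- heatmap_labeling_matrix(full)
  expect_equal(hm["CIT", "ctl"], 1.0)
  expect_equal(hm["LAC", "ctl"], 2.0)
  mixed <- fix_table()
  mixed$amount[mixed$metabolite == "LAC"] <- c(60, 0, 0, 40)      # 40% labeled
  expect_equal(heatmap_labeling_matrix(mixed)["LAC", "ctl"], 1.4)
  expect_true(all(hm >= 1 & hm <= 2))
})

test_that("product/substrate ratios divide labeled totals", {
  tab <- data.frame(
    metabolite = rep(c("FBP", "F6P"), each = 3),
    pathway = "glycolysis", condition = "ctl", tracer = "U13C6",
    mass_shift = rep(c(0, 3, 6), 2),
    amount = c(1, 10, 20, 2, 5, 5))
  expect_equal(product_substrate_ratio(tab, "FBP", "F6P", "ctl"), 3)
  eq <- tab; eq$amount <- rep(c(0, 5, 5), 2)
  expect_equal(product_substrate_ratio(eq, "FBP", "F6P", "ctl"), 1)
  none <- tab; none$amount[none$metabolite == "F6P"] <- 0
  expect_error(product_substrate_ratio(none, "FBP", "F6P", "ctl"),
               "undefined ratio")
})

test_that("MDV extraction feeds the fitter the normalized fractions", {
  tab <- fix_table()
  mdvs <- mdvs_from_table(tab, c("LAC", "CIT"), "ctl")
  expect_equal(mdvs$LAC, c(0.25, 0, 0, 0.75))
  expect_equal(length(mdvs$CIT), 7L)
  expect_equal(sum(mdvs$CIT), 1)
})
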