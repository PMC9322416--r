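test_that("lifetime partition matches the hand-computed 4-male example", {
  tab <- lifetime_partition(toy4_life())
  get <- function(cp, col) tab[[col]][tab$component == cp]
  # n-1 denominators: var(EGP) = 2/3, var(WGP) = 2, cov = 0, var(LRS) = 8/3
  expect_equal(get("EGP", "raw"), 2 / 3)
  expect_equal(get("WGP", "raw"), 2)
  expect_equal(get("EGPxWGP", "raw"), 0)
  expect_equal(get("RS", "raw"), 8 / 3)
  # standardized by mean LRS = 2: 1/6, 1/2, 0, 2/3
  expect_equal(get("EGP", "standardized"), 1 / 6)
  expect_equal(get("WGP", "standardized"), 1 / 2)
  expect_equal(get("EGPxWGP", "standardized"), 0)
  expect_equal(get("RS", "standardized"), 2 / 3)
  expect_true(check_decomposition(tab)[["eq1_identity"]])
})

test_that("lifetime partition handles edge conditions", {
  life <- toy4_life()
  same <- life
  same[, c("lifetime_egp", "lifetime_wgp", "lifetime_rs",
           "lifetime_rs_ap")] <- rep(c(1L, 1L, 2L, 1L), each = 4)
  tab <- lifetime_partition(same)
  expect_true(all(tab$raw == 0))

  zero <- life
  zero[, c("lifetime_egp", "lifetime_wgp", "lifetime_rs")] <- 0L
  expect_error(lifetime_partition(zero), "mean is zero")
  expect_silent(lifetime_partition(zero, standardize_by = "none"))
  expect_error(lifetime_partition(life[1, ]), "at least 2")
})

test_that("denominator convention switch rescales by (n-1)/n", {
  t1 <- lifetime_partition(toy4_life(), denom = "n-1")
  t2 <- lifetime_partition(toy4_life(), denom = "n")
  expect_equal(t2$raw, t1$raw * 3 / 4)
})

test_that("additive partition matches the hand-computed 3-male toy", {
  mat <- build_age_matrix(toy3_records(), "additive", n_classes = 2L)
  tab <- additive_partition(mat)
  rs_age <- tab[tab$component == "RS" & tab$level == "age", ]
  expect_equal(rs_age$raw, c(1 / 3, 4 / 3))
  rs_btw <- tab[tab$component == "RS" & tab$level == "between_age", ]
  expect_equal(rs_btw$raw, -2 / 3)
  life_rs <- tab[tab$component == "RS" & tab$level == "lifetime", ]
  expect_equal(life_rs$raw, 1)
  # standardized by mean LRS = 2
  expect_equal(rs_age$standardized, c(1 / 12, 1 / 3))
  expect_equal(rs_btw$standardized, -1 / 6)
  expect_equal(life_rs$standardized, 1 / 4)
  expect_true(all(check_decomposition(tab)))
  expect_error(additive_partition(
    build_age_matrix(toy3_records(), "independent", n_classes = 2L)),
    "additive-mode")
})

test_that("single-age additive partition reduces to the lifetime partition", {
  rec <- toy3_records()
  rec <- rec[rec$age_class == 1L, ]
  mat <- build_age_matrix(rec, "additive", n_classes = 1L)
  add <- additive_partition(mat)
  life <- lifetime_partition(aggregate_lifetime(rec))
  for (cp in c("EGP", "WGP", "EGPxWGP", "RS", "RS_ap")) {
    expect_equal(add$raw[add$component == cp & add$level == "lifetime"],
                 life$raw[life$component == cp], info = cp)
  }
})

test_that("independent partition computes survivor-only standardized terms", {
  mat <- build_age_matrix(toy3_records(), "independent", n_classes = 2L)
  tab <- independent_partition(mat)
  a1 <- tab[tab$age_i == 1L, ]
  expect_equal(a1$raw[a1$component == "RS"], 1 / 3)
  expect_equal(a1$mean[a1$component == "RS"], 2 / 3)
  expect_equal(a1$standardized[a1$component == "RS"], 0.75)
  expect_identical(unique(a1$n), 3L)
  a2 <- tab[tab$age_i == 2L, ]   # survivors B, C both have RS = 2
  expect_equal(a2$raw[a2$component == "RS"], 0)
  expect_identical(unique(a2$n), 2L)
  expect_true(all(check_decomposition(tab)))
  expect_error(independent_partition(
    build_age_matrix(toy3_records(), "additive", n_classes = 2L)),
    "independent-mode")
})

test_that("ages with fewer than two survivors yield NA, never zero", {
  rec <- toy3_records()
  rec <- rbind(rec, data.frame(male_id = "B", cohort_year = 2000L,
                               age_class = 3L, is_dominant = TRUE,
                               egp = 1L, wgp = 0L, rs_ap = 0L))
  mat <- build_age_matrix(rec, "independent", n_classes = 3L)
  tab <- independent_partition(mat)
  a3 <- tab[tab$age_i == 3L, ]
  expect_true(all(is.na(a3$raw)))
  expect_identical(unique(a3$n), 1L)
})

test_that("all covariance terms match a naive double-loop oracle", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    A <- sample(2:3, 1)
    rec <- random_records(n, A)
    mat <- build_age_matrix(rec, "additive", n_classes = A)
    tab <- additive_partition(mat, standardize_by = "none")
    for (i in seq_len(A)) {
      expect_equal(tab$raw[tab$component == "EGP" & tab$level == "age" &
                             tab$age_i == i],
                   naive_cov(mat$EGP[, i], mat$EGP[, i]))
      expect_equal(tab$raw[tab$component == "EGPxWGP" & tab$level == "age" &
                             tab$age_i == i],
                   2 * naive_cov(mat$EGP[, i], mat$WGP[, i]))
    }
    for (i in seq_len(A - 1)) {
      for (j in seq(i + 1, A)) {
        expect_equal(tab$raw[tab$component == "WGP" &
                               tab$level == "between_age" &
                               tab$age_i == i & tab$age_j == j],
                     2 * naive_cov(mat$WGP[, i], mat$WGP[, j]))
        expect_equal(tab$raw[tab$component == "EGPxWGP" &
                               tab$level == "between_age" &
                               tab$age_i == j & tab$age_j == i],
                     2 * naive_cov(mat$EGP[, j], mat$WGP[, i]))
      }
    }
  }
})

test_that("standardized tables are invariant to uniform count scaling", {
  rec <- random_records(30, 4)
  k <- 3L
  scaled <- rec
  scaled[, c("egp", "wgp", "rs_ap")] <- scaled[, c("egp", "wgp", "rs_ap")] * k
  t1 <- lifetime_partition(aggregate_lifetime(rec))
  t2 <- lifetime_partition(aggregate_lifetime(scaled))
  expect_equal(t2$standardized, t1$standardized)
  a1 <- additive_partition(build_age_matrix(rec, "additive", 4L))
  a2 <- additive_partition(build_age_matrix(scaled, "additive", 4L))
  expect_equal(a2$standardized, a1$standardized)
  i1 <- independent_partition(build_age_matrix(rec, "independent", 4L))
  i2 <- independent_partition(build_age_matrix(scaled, "independent", 4L))
  expect_equal(i2$standardized, i1$standardized)
})

test_that("with no deaths, additive and independent within-age terms agree", {
  set.seed(5)
  n <- 20L; A <- 3L
  rec <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(male_id = sprintf("m%02d", i), cohort_year = 2000L,
               age_class = 1:A, is_dominant = TRUE,
               egp = rpois(A, 1), wgp = rpois(A, 1), rs_ap = rpois(A, 1))
  }))
  add <- additive_partition(build_age_matrix(rec, "additive", A),
                            standardize_by = "none")
  ind <- independent_partition(build_age_matrix(rec, "independent", A),
                               standardize = FALSE)
  for (i in seq_len(A)) {
    for (cp in c("EGP", "WGP", "RS", "RS_ap", "EGPxWGP")) {
      expect_equal(ind$raw[ind$component == cp & ind$age_i == i],
                   add$raw[add$component == cp & add$level == "age" &
                             add$age_i == i], info = paste(cp, i))
    }
  }
})

test_that("percent contribution and variance ratio match reported rounding", {
  expect_identical(percent_contribution(0.71, 2.08), 34)
  expect_identical(percent_contribution(0.82, 2.08), 39)
  expect_identical(percent_contribution(0.55, 2.08), 26)
  expect_identical(percent_contribution(1, 1), 100)
  expect_equal(percent_contribution(0.71, 2.08, digits = NULL),
               100 * 0.71 / 2.08)
  expect_error(percent_contribution(1, 0), "zero total")
  expect_equal(round(variance_ratio(2.08, 1.75), 2), 1.19)
  expect_equal(round(variance_ratio(0.55, 0.82), 2), 0.67)
  expect_equal(variance_ratio(1.3, 1.3), 1)
  expect_error(variance_ratio(1, 0), "zero denominator")
})

test_that("presentation rounding keeps one significant figure below 0.01", {
  expect_equal(round_report(c(0.236, 0.0043, 0.00021, 0, -0.0062)),
               c(0.24, 0.004, 0.0002, 0, -0.006))
})
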