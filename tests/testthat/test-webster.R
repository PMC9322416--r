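make_summaries <- function(M_wg, N_wg, P_wg, M_eg, N_eg, P_eg) {
  n <- length(M_wg)
  ids <- sprintf("m%02d", seq_len(n))
  rbind(
    data.frame(male_id = ids, pathway = "within-group", M = M_wg, N = N_wg,
               P = P_wg, T = M_wg * N_wg * P_wg, stringsAsFactors = FALSE),
    data.frame(male_id = ids, pathway = "extra-group", M = M_eg, N = N_eg,
               P = P_eg, T = M_eg * N_eg * P_eg, stringsAsFactors = FALSE))
}

test_that("doubly successful males are selected by both lifetime totals", {
  life <- toy4_life()   # (egp, wgp): (0,0), (1,1), (2,0), (1,3)
  kept <- select_successful(life)
  expect_setequal(kept$male_id, c("b", "d"))
  expect_identical(nrow(select_successful(life[0, ])), 0L)
})

test_that("mate summaries satisfy the T = M * N * P identity exactly", {
  mates <- data.frame(
    male_id = c("x", "x", "x", "y"),
    pathway = c("within-group", "within-group", "extra-group", "extra-group"),
    mate_id = c("f1", "f2", "f3", "f4"),
    offspring_by_mate = c(3L, 2L, 1L, 4L),
    offspring_sired = c(2L, 1L, 1L, 2L), stringsAsFactors = FALSE)
  s <- mate_pathway_summary(mates)
  expect_equal(s$T, s$M * s$N * s$P)
  expect_true(all(s$P >= 0 & s$P <= 1))
  x_wg <- s[s$male_id == "x" & s$pathway == "within-group", ]
  expect_equal(x_wg$M, 2)
  expect_equal(x_wg$N, 2.5)
  expect_equal(x_wg$P, 3 / 5)

  zero_brood <- rbind(mates, data.frame(
    male_id = "y", pathway = "within-group", mate_id = "f5",
    offspring_by_mate = 0L, offspring_sired = 0L))
  expect_warning(s2 <- mate_pathway_summary(zero_brood), "zero-brood")
  expect_false("y" %in% s2$male_id)
})

test_that("identical males produce an all-zero decomposition", {
  s <- make_summaries(rep(2, 4), rep(1.5, 4), rep(0.5, 4),
                      rep(1, 4), rep(2, 4), rep(0.5, 4))
  tab <- webster_decomposition(s)
  expect_true(all(tab$raw[tab$pathway != "cross"] == 0))
  expect_equal(tab$raw[tab$term == "var_LRS"], 0)
})

test_that("emitted terms always sum exactly to var(T)", {
  # 3-male toy with extra-group totals T = {1, 2, 4}: var(T) = 7/3
  s <- make_summaries(M_wg = c(1, 1, 2), N_wg = c(1, 2, 1.5),
                      P_wg = c(1, 0.5, 1),
                      M_eg = c(1, 2, 2), N_eg = c(1, 1, 2),
                      P_eg = c(1, 1, 1))
  tab <- webster_decomposition(s)
  eg <- tab[tab$pathway == "extra-group", ]
  expect_equal(eg$raw[eg$term == "var_T"], 7 / 3)
  expect_equal(sum(eg$raw[eg$term != "var_T"]), 7 / 3)
  expect_equal(eg$raw[eg$term == "var_T"],
               naive_cov(c(1, 2, 4), c(1, 2, 4)))

  # random inputs: the exact-sum property is structural
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    s <- make_summaries(sample(1:4, n, TRUE), runif(n, 1, 3), runif(n),
                        sample(1:4, n, TRUE), runif(n, 1, 3), runif(n))
    tab <- webster_decomposition(s)
    for (pw in c("within-group", "extra-group")) {
      sub <- tab[tab$pathway == pw, ]
      expect_equal(sum(sub$raw[sub$term != "var_T"]),
                   sub$raw[sub$term == "var_T"])
      d <- s[s$pathway == pw, ][seq_len(n), ]
      expect_equal(sub$raw[sub$term == "var_T"], var(d$M * d$N * d$P))
    }
    # pathway totals and their covariance reassemble var(LRS) of the subset
    wg <- s[s$pathway == "within-group", ]; eg <- s[s$pathway == "extra-group", ]
    expect_equal(tab$raw[tab$term == "var_LRS"], var(wg$T + eg$T))
    expect_equal(tab$raw[tab$term == "var_T"][1] +
                   tab$raw[tab$term == "var_T"][2] +
                   tab$raw[tab$term == "2cov_T"], var(wg$T + eg$T))
  }
})

test_that("perturbing only mate number loads variance on M-terms", {
  s <- make_summaries(M_wg = c(1, 2, 3, 4), N_wg = rep(2, 4),
                      P_wg = rep(0.5, 4),
                      M_eg = rep(2, 4), N_eg = rep(1, 4), P_eg = rep(0.5, 4))
  tab <- webster_decomposition(s)
  wg <- tab[tab$pathway == "within-group", ]
  expect_gt(wg$raw[wg$term == "var_M"], 0)
  off_M <- setdiff(wg$term, c("var_M", "var_T"))
  expect_true(all(wg$raw[wg$term %in% off_M] == 0))
  expect_equal(wg$raw[wg$term == "var_M"], wg$raw[wg$term == "var_T"])
})

test_that("doubling fecundity quadruples var(T) but keeps the exact sum", {
  set.seed(3)
  n <- 6
  s <- make_summaries(sample(1:3, n, TRUE), runif(n, 1, 2), runif(n),
                      sample(1:3, n, TRUE), runif(n, 1, 2), runif(n))
  s2 <- s
  s2$N <- 2 * s2$N
  s2$T <- s2$M * s2$N * s2$P
  t1 <- webster_decomposition(s)
  t2 <- webster_decomposition(s2)
  for (pw in c("within-group", "extra-group")) {
    v1 <- t1$raw[t1$pathway == pw & t1$term == "var_T"]
    v2 <- t2$raw[t2$pathway == pw & t2$term == "var_T"]
    expect_equal(v2, 4 * v1)
    sub <- t2[t2$pathway == pw, ]
    expect_equal(sum(sub$raw[sub$term != "var_T"]),
                 sub$raw[sub$term == "var_T"])
  }
})

test_that("synthetic mate detail is consistent with the lifetime totals", {
  pop <- simulate_population(simulator_config(n_males = 500, seed = 19))
  succ <- select_successful(pop$life)
  expect_gt(nrow(succ), 0)
  expect_lt(nrow(succ), 500)
  mates <- simulate_mates(succ, seed = 2)
  s <- mate_pathway_summary(mates)
  merged <- merge(s[s$pathway == "extra-group", ], succ, by = "male_id")
  expect_equal(merged$T, as.numeric(merged$lifetime_egp))
  expect_equal(s$T, s$M * s$N * s$P)
  tab <- webster_decomposition(s)
  expect_true(all(is.finite(tab$raw)))
})
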