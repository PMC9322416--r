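# in-code fixtures shared across the suite

# four males observed at one age; lifetime (EGP, WGP) = (0,0),(1,1),(2,0),(1,3)
toy4_life <- function() {
  data.frame(male_id = c("a", "b", "c", "d"), cohort_year = 2000L,
             lifespan_class = 1L, age_first_dominance = 1L,
             lifetime_egp = c(0L, 1L, 2L, 1L),
             lifetime_wgp = c(0L, 1L, 0L, 3L),
             lifetime_rs = c(0L, 2L, 2L, 4L),
             lifetime_rs_ap = c(0L, 1L, 0L, 3L),
             stringsAsFactors = FALSE)
}

# three males over two ages; male A dies after age 1:
#   A: (egp, wgp) = (1, 0);  B: (0, 1) then (1, 1);  C: (0, 0) then (2, 0)
toy3_records <- function() {
  data.frame(
    male_id = c("A", "B", "B", "C", "C"),
    cohort_year = 2000L,
    age_class = c(1L, 1L, 2L, 1L, 2L),
    is_dominant = TRUE,
    egp = c(1L, 0L, 1L, 0L, 2L),
    wgp = c(0L, 1L, 1L, 0L, 0L),
    rs_ap = c(1L, 1L, 2L, 0L, 1L),
    stringsAsFactors = FALSE)
}

# random small record sets for property tests
random_records <- function(n_males, n_ages, lambda = 1.2) {
  ids <- sprintf("m%03d", seq_len(n_males))
  rows <- lapply(seq_len(n_males), function(i) {
    lifespan <- sample.int(n_ages, 1L)
    ages <- seq_len(lifespan)
    dom <- ages >= sample.int(lifespan, 1L)
    data.frame(male_id = ids[i], cohort_year = 2000L, age_class = ages,
               is_dominant = dom,
               egp = rpois(lifespan, lambda) * dom,
               wgp = rpois(lifespan, lambda) * dom,
               rs_ap = rpois(lifespan, lambda) * dom,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# naive double-loop (co)variance oracle, n-1 denominator
naive_cov <- function(x, y) {
  x <- unname(x)
  y <- unname(y)
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  s <- 0
  for (i in seq_len(n)) s <- s + (x[i] - mx) * (y[i] - my)
  s / (n - 1)
}
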