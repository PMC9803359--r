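test_that("frequency matrices equal hand tallies without pseudocount", {
  fm <- freq_matrix(c("GUAAG", "GUAAG"), positions = 1:5)
  expect_equal(fm$G[fm$position == 1], 1)
  expect_equal(fm$A[fm$position == 4], 1)

  fm2 <- freq_matrix(c("GUAAG", "GUAUG"), positions = 1:5)
  expect_equal(fm2$A[fm2$position == 4], 0.5)
  expect_equal(fm2$U[fm2$position == 4], 0.5)

  # 10 hand-written sites vs an explicit manual count
  sites <- c("AAGGV", "ACGGU", "AGGGU", "AUGGU", "CAGGU",
             "CCGGU", "CGGGU", "CUGGU", "GAGGU", "GCGGU")
  fm3 <- freq_matrix(sites, positions = 1:5)
  expect_equal(fm3$A[fm3$position == 1], 4 / 10)
  expect_equal(fm3$C[fm3$position == 1], 4 / 10)
  expect_equal(fm3$G[fm3$position == 1], 2 / 10)
  expect_equal(fm3$A[fm3$position == 2], 3 / 10)
  # the ambiguity code V at +5 is excluded from that position's denominator
  expect_equal(fm3$U[fm3$position == 5], 9 / 9)
  expect_equal(unname(rowSums(as.matrix(fm3[c("A", "C", "G", "U")]))),
               rep(1, 5), tolerance = 1e-9)
  expect_error(freq_matrix(character(0), positions = 1), "empty")
})

test_that("a union's frequency matrix is the count-weighted average of its parts", {
  a <- random_windows(40, len = 5, seed = 11)
  b <- random_windows(60, len = 5, seed = 12)
  fa <- as.matrix(freq_matrix(a, positions = 1:5)[c("A", "C", "G", "U")])
  fb <- as.matrix(freq_matrix(b, positions = 1:5)[c("A", "C", "G", "U")])
  fu <- as.matrix(freq_matrix(c(a, b), positions = 1:5)[c("A", "C", "G", "U")])
  expect_equal(fu, (40 * fa + 60 * fb) / 100, tolerance = 1e-12)
})

test_that("G-tests match hand arithmetic and are additive over positions", {
  same <- g_test_composition(c("AG", "CU"), c("AG", "CU"), positions = 1:2)
  expect_equal(same$g, 0)
  expect_equal(same$p_value, 1)

  gt <- g_test_composition(rep("A", 4), rep("U", 4), positions = 1)
  expect_equal(gt$g, 16 * log(2), tolerance = 1e-12)
  expect_equal(gt$df, 1L)  # only two observed bases

  a <- random_windows(30, len = 4, seed = 21)
  b <- random_windows(30, len = 4, seed = 22)
  total <- g_test_composition(a, b, positions = 1:4)
  singles <- lapply(1:4, function(k) {
    g_test_composition(substr(a, k, k), substr(b, k, k), positions = 1)
  })
  expect_equal(total$g, sum(vapply(singles, `[[`, numeric(1), "g")))
  expect_equal(total$df, sum(vapply(singles, `[[`, integer(1), "df")))

  # matches the independent margin-based oracle per position
  o <- oracle_g(substr(a, 2, 2), substr(b, 2, 2))
  expect_equal(singles[[2]]$g, o$g, tolerance = 1e-12)
  expect_equal(singles[[2]]$df, as.integer(o$df))
})

test_that("G-test p-values agree with a permutation null on small fixtures", {
  set.seed(404)
  a <- sample(c("A", "C", "G", "U"), 25, replace = TRUE,
              prob = c(0.4, 0.2, 0.2, 0.2))
  b <- sample(c("A", "C", "G", "U"), 25, replace = TRUE,
              prob = c(0.2, 0.2, 0.2, 0.4))
  obs <- g_test_composition(a, b, positions = 1)
  pooled <- c(a, b)
  perm_g <- replicate(2000, {
    idx <- sample(50, 25)
    oracle_g(pooled[idx], pooled[-idx])$g
  })
  p_perm <- mean(perm_g >= obs$g - 1e-12)
  expect_lt(abs(p_perm - obs$p_value), 0.02)
})

test_that("class contingency tables count every site once and order by score", {
  sim <- simulate_sites(n_sites = 2000, seed = 41)
  w <- tibble(site_kind = "five_prime", seq = sim$sites$seq)
  cc <- class_contingency(w)
  expect_equal(sum(cc$counts), 2000)
  expect_equal(rownames(cc$counts), c("0", "1", "2"))  # index order, no PSSM

  p5 <- build_pssm(w, positions = -2:-1)
  p6 <- build_pssm(w, positions = 3:5)
  cc2 <- class_contingency(w, p5, p6)
  cl <- classify_sites(w)
  sc <- score_sites(w, p5, p6)
  mean_ll5 <- tapply(sc$u5_ll, cl$u5_class, mean)
  expect_equal(rownames(cc2$counts),
               names(sort(mean_ll5, decreasing = TRUE)))
})

test_that("the +4 direction table recovers planted separation rates", {
  # all pairs follow the A(+4)-lost / B(+4)-gained rule
  lost <- rep("CAGGUAAG", 10)   # +4 = A
  gained <- rep("CAGGUAUG", 10) # +4 = U
  tab <- plus4_direction_table(tibble(lost_seq = lost, gained_seq = gained))
  expect_equal(tab$separation_rate, 1)
  expect_equal(unname(tab$counts["reduced_usage", "A"]), 10)
  expect_equal(unname(tab$counts["increased_usage", "not_A"]), 10)
  expect_equal(sum(tab$counts), 2 * 10)

  # planted 80% rule-consistent pairs
  set.seed(7)
  n <- 400
  consistent <- runif(n) < 0.8
  lostb <- ifelse(consistent, "CAGGUAAG", "CAGGUAUG")
  gainedb <- ifelse(consistent, "CAGGUAUG", "CAGGUAAG")
  tab2 <- plus4_direction_table(tibble(lost_seq = lostb, gained_seq = gainedb))
  expect_lt(abs(tab2$separation_rate - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})

test_that("Spearman correlation handles perfect, null, and transformed inputs", {
  expect_equal(score_correlation(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  set.seed(12)
  x <- runif(1000); y <- runif(1000)
  expect_lt(abs(score_correlation(x, y)$rho), 0.08)
  d <- tibble(u5_ll = rnorm(100), u6_ll = rnorm(100))
  r1 <- score_correlation(d)$rho
  r2 <- score_correlation(d |> mutate(u5_ll = exp(u5_ll),
                                      u6_ll = u6_ll^3))$rho
  expect_equal(r1, r2)
  expect_error(score_correlation(c(1, 2), c(2, 1)), "at least 3")
})

test_that("the two-class mixture shows the U5/U6 anticorrelation", {
  sim <- simulate_sites(n_sites = 4000, seed = 51)
  sc <- score_sites(tibble(site_kind = "five_prime", seq = sim$sites$seq))
  res <- score_correlation(sc)
  expect_lt(res$rho, -0.3)
  expect_lt(res$p.value, 1e-10)
  # separation strengthens the anticorrelation
  sim_weak <- simulate_sites(n_sites = 4000, consensus_prob = 0.5, seed = 52)
  sc_weak <- score_sites(tibble(site_kind = "five_prime",
                                seq = sim_weak$sites$seq))
  expect_lt(res$rho, score_correlation(sc_weak)$rho)
})

test_that("frequency matrices serialize to logo-compatible TSV", {
  fm <- freq_matrix(random_windows(20, seed = 61),
                    positions = c(-3:-1, 1:5))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_freq_matrix_tsv(fm, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(back$position, c(-3:-1, 1:5))
  expect_equal(back$A, fm$A, tolerance = 1e-12)
})
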