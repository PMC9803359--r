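make_variants <- function(ref, alt) {
  tibble(chrom = "chr2", pos = seq_along(ref) * 100L, ref = ref, alt = alt,
         normal_ref = 10L, normal_alt = 10L,
         mutant_ref = 10L, mutant_alt = 10L) |>
    mutate(normal_af = 0.5, mutant_af = 0.5,
           is_ems_transition = (ref == "G" & alt == "A") |
             (ref == "C" & alt == "T"))
}

test_that("EMS filtering keeps G>A (and C>T by default) transitions only", {
  v <- make_variants(ref = c("G", "C", "A", "G"),
                     alt = c("A", "T", "G", "T"))
  kept <- suppressMessages(filter_ems(v))
  expect_equal(nrow(kept), 2L)
  expect_setequal(paste0(kept$ref, ">", kept$alt), c("G>A", "C>T"))

  strict <- suppressMessages(filter_ems(v, strict = TRUE))
  expect_equal(nrow(strict), 1L)
  expect_equal(strict$ref, "G")

  none <- make_variants(ref = c("A", "T"), alt = c("G", "C"))
  expect_warning(suppressMessages(filter_ems(none)), "no EMS")
})

test_that("indels and multi-allelic records are dropped with a count", {
  v <- make_variants(ref = c("G", "GA", "G"), alt = c("A", "A", "A,T"))
  expect_message(kept <- filter_ems(v), "multi-allelic or indel")
  expect_equal(nrow(kept), 1L)
})

test_that("the pool-contrast G statistic matches hand arithmetic", {
  even <- tibble(normal_ref = 10, normal_alt = 10,
                 mutant_ref = 10, mutant_alt = 10)
  expect_equal(pool_g_test(even)$g, 0)

  extreme <- tibble(normal_ref = 20, normal_alt = 0,
                    mutant_ref = 0, mutant_alt = 20)
  expect_equal(pool_g_test(extreme)$g, 80 * log(2), tolerance = 1e-12)

  v <- tibble(normal_ref = 13, normal_alt = 7, mutant_ref = 4,
              mutant_alt = 16)
  g1 <- pool_g_test(v)$g
  # swapping pools and swapping allele labels both leave G unchanged
  g2 <- pool_g_test(tibble(normal_ref = 4, normal_alt = 16,
                           mutant_ref = 13, mutant_alt = 7))$g
  g3 <- pool_g_test(tibble(normal_ref = 7, normal_alt = 13,
                           mutant_ref = 16, mutant_alt = 4))$g
  expect_equal(g1, g2)
  expect_equal(g1, g3)

  zero <- tibble(normal_ref = 0, normal_alt = 0, mutant_ref = 10,
                 mutant_alt = 10)
  expect_true(is.na(pool_g_test(zero)$g))
})

test_that("tri-cube weights follow the closed form", {
  h <- 1e6
  expect_equal(tricube_weight(0, h), 1)
  expect_equal(tricube_weight(h, h), 0)
  expect_equal(tricube_weight(h / 2, h), (7 / 8)^3)
  expect_equal(tricube_weight(-h / 2, h), (7 / 8)^3)
  expect_equal(tricube_weight(2 * h, h), 0)
})

test_that("smoothing identities: isolated SNPs, hand-computed means, convexity", {
  solo <- tibble(chrom = "c", pos = 5L, g = 3.7)
  expect_equal(smooth_track(solo)$g_smooth, 3.7)

  # three SNPs at 0, h/2, h with G = (0, 8, 0): the middle value is a
  # weighted mean with weights (0.6699.., 1, 0.6699..)
  h <- 1e6
  tr <- smooth_track(tibble(chrom = "c", pos = c(1, h / 2 + 1, h + 1),
                            g = c(0, 8, 0)), window = 2 * h)
  w <- (7 / 8)^3
  expect_equal(tr$g_smooth[2], 8 / (1 + 2 * w), tolerance = 1e-9)

  set.seed(5)
  big <- tibble(chrom = "c", pos = sort(sample.int(5e6, 300)),
                g = rexp(300))
  sm <- smooth_track(big)
  expect_true(all(sm$g_smooth >= min(big$g) - 1e-12))
  expect_true(all(sm$g_smooth <= max(big$g) + 1e-12))

  # half-width reinterpretation widens the kernel support
  sm_wide <- smooth_track(big, window = 2e6, half_width = TRUE)
  expect_false(isTRUE(all.equal(sm$g_smooth, sm_wide$g_smooth)))
})

test_that("interval calling returns the contiguous near-peak region", {
  tr <- structure(
    tibble(chrom = "c", pos = as.integer(1:11 * 1000),
           g_raw = c(1, 1, 2, 8, 9, 10, 9, 8, 2, 1, 1),
           g_smooth = c(1, 1, 2, 8, 9, 10, 9, 8, 2, 1, 1)),
    class = c("bsa_track", class(tibble())))
  iv <- call_interval(tr, peak_fraction = 0.85)
  expect_equal(iv$start, 5000L)
  expect_equal(iv$end, 7000L)
  expect_equal(iv$peak_pos, 6000L)

  # peak_fraction 1 degenerates to the argmax SNP
  iv1 <- call_interval(tr, peak_fraction = 1)
  expect_equal(iv1$start, 6000L)
  expect_equal(iv1$end, 6000L)

  # two tied peaks: the widest qualifying run wins, with a warning
  tr2 <- structure(
    tibble(chrom = "c", pos = as.integer(1:9 * 1000),
           g_raw = c(10, 1, 1, 10, 10, 10, 1, 1, 10),
           g_smooth = c(10, 1, 1, 10, 10, 10, 1, 1, 10)),
    class = c("bsa_track", class(tibble())))
  expect_warning(iv2 <- call_interval(tr2, peak_fraction = 0.95), "tied")
  expect_equal(iv2$start, 4000L)
  expect_equal(iv2$end, 6000L)

  flat <- structure(
    tibble(chrom = "c", pos = as.integer(1:5 * 1000),
           g_raw = rep(2, 5), g_smooth = rep(2, 5)),
    class = c("bsa_track", class(tibble())))
  expect_warning(ivf <- call_interval(flat), "flat")
  expect_equal(c(ivf$start, ivf$end), c(1000L, 5000L))
})

test_that("pool allele fractions follow the recessive segregation model", {
  sim <- simulate_bsa(n_snps = 4000, causal_pos = 10e6, seed = 88)
  v <- sim$variants
  d_mb <- abs(v$pos - 10e6) / 1e6
  # near-causal neighbourhood (r < 0.01, ~80 SNPs averaged)
  at_causal <- d_mb < 0.2
  # mutant pool approaches fixation at the causal locus, normal pool 1/3
  expect_gt(mean(v$mutant_af[at_causal]), 0.95)
  expect_lt(abs(mean(v$normal_af[at_causal]) - 1 / 3), 0.05)
  # along the chromosome, binned mean fractions track the Haldane-model
  # expectations (bins of ~200 SNPs: 5 sigma is about 0.03)
  r <- 0.5 * (1 - exp(-2 * 0.05 * d_mb))
  bin <- cut(v$pos, breaks = 20)
  dev_mut <- abs(tapply(v$mutant_af, bin, mean) - tapply(1 - r, bin, mean))
  dev_norm <- abs(tapply(v$normal_af, bin, mean) -
                    tapply(1 / 3 + r / 3, bin, mean))
  expect_lt(max(dev_mut), 0.03)
  expect_lt(max(dev_norm), 0.03)

  # with recombination fast enough to unlink the chromosome ends, the two
  # pools' fractions converge to 1/2 far from the causal locus
  sim2 <- simulate_bsa(n_snps = 4000, causal_pos = 10e6, rec_per_mb = 0.3,
                       seed = 89)
  far <- abs(sim2$variants$pos - 10e6) > 8e6
  expect_lt(abs(mean(sim2$variants$mutant_af[far]) -
                  mean(sim2$variants$normal_af[far])), 0.02)
  expect_lt(abs(mean(sim2$variants$mutant_af[far]) - 0.5), 0.02)
})

test_that("simulated VCFs round-trip through the VCF reader", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  sim <- simulate_bsa(n_snps = 80, seed = 9, vcf = vcf)
  v <- read_pool_vcf(vcf)
  expect_equal(v$pos, sim$variants$pos)
  expect_equal(v$ref, sim$variants$ref)
  expect_equal(v$normal_ref, sim$variants$normal_ref)
  expect_equal(v$mutant_alt, sim$variants$mutant_alt)
  expect_equal(v$is_ems_transition, sim$variants$is_ems_transition)
  expect_error(read_pool_vcf(vcf, pool_mutant = "missing"), "not in VCF")
})

test_that("the scan localizes a planted causal locus", {
  sim <- simulate_bsa(seed = 123)
  tr <- smooth_track(pool_g_test(sim$variants))
  iv <- call_interval(tr)
  expect_lt(abs(iv$peak_pos - sim$truth$causal_pos), 1e6)
  # the raw track is noisy; smoothing must reduce roughness
  expect_lt(stats::sd(diff(tr$g_smooth)), stats::sd(diff(tr$g_raw)))
})
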