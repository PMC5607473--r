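test_that("the simulator is deterministic given a seed", {
  a <- simulate_dataset(sim_config(n_families = 5, seed = 17))
  b <- simulate_dataset(sim_config(n_families = 5, seed = 17))
  expect_identical(a$evidence, b$evidence)
  expect_identical(a$truth$dnms, b$truth$dnms)
  expect_identical(a$pair_counts, b$pair_counts)
  c <- simulate_dataset(sim_config(n_families = 5, seed = 18))
  expect_false(identical(a$evidence, c$evidence))
})

test_that("pedigree structure matches the configuration", {
  ds <- simulate_dataset(sim_config(n_families = 10, n_twin_pairs = 3,
                                    offspring_per_proband = 2L, seed = 4))
  fams <- find_three_generation_families(ds$pedigree)
  expect_length(fams, 10L)
  expect_true(all(vapply(fams, function(f) length(f$offspring), 1L) == 2L))
  tg <- ds$pedigree$records$twin_group
  expect_identical(length(unique(tg[!is.na(tg)])), 3L)
  # map invariants hold
  for (ch in unique(ds$genetic_map$chrom)) {
    g <- ds$genetic_map[ds$genetic_map$chrom == ch, ]
    expect_false(is.unsorted(g$pos, strictly = TRUE))
    expect_false(is.unsorted(g$cM))
  }
})

test_that("zero rates produce empty truth and zero candidates", {
  ds <- simulate_dataset(sim_config(n_families = 5, dnm_rate = 0,
                                    artifact_rate = 0, seed = 3))
  expect_identical(nrow(ds$truth$dnms), 0L)
  expect_identical(nrow(ds$variants), 0L)
  res <- run_pipeline(ds)
  expect_identical(unname(res$report["n_candidates_raw"]), 0L)
  expect_identical(unname(res$report["n_high_quality"]), 0L)
})

test_that("no recombination passes one parental haplotype per chromosome", {
  cfg <- sim_config(n_families = 6, cm_per_mb = 0, seed = 8)
  ds <- simulate_dataset(cfg)
  inh <- ds$inheritance
  v <- ds$variants
  inh$chrom <- v$chrom[match(inh$site_id, v$site_id)]
  # within each offspring and chromosome, every site shows the same
  # proband haplotype
  agg <- tapply(inh$proband_hap, paste(inh$offspring, inh$chrom),
                function(x) length(unique(x)))
  expect_true(all(agg == 1L))
})

test_that("planted DNM counts follow the configured Poisson rate", {
  counts <- integer(6)
  for (s in seq_along(counts)) {
    ds <- simulate_dataset(sim_config(n_families = 30, artifact_rate = 0,
                                      seed = 100 + s))
    counts[s] <- nrow(ds$truth$dnms)
  }
  lambda <- 30 * 2 * 4          # families x gametes x rate
  se <- sqrt(lambda)
  expect_lt(abs(mean(counts) - lambda), 3 * se / sqrt(length(counts)))
})

test_that("deep error-free coverage concentrates het allelic balance", {
  ds <- simulate_dataset(sim_config(n_families = 4, coverage = 1000,
                                    seq_error = 0, artifact_rate = 0,
                                    seed = 12))
  ev <- ds$evidence
  tr_key <- paste(ds$truth$dnms$site_id, ds$truth$dnms$proband)
  hets <- ev[paste(ev$site_id, ev$id) %in% tr_key, ]
  ab <- allelic_balance(hets$ref_reads, hets$alt_reads)
  expect_true(all(abs(ab - 0.5) < 0.05))
})

test_that("artifact evidence behaves as configured", {
  ds <- simulate_dataset(sim_config(n_families = 40, dnm_rate = 0,
                                    artifact_rate = 10, oxog_fraction = 1,
                                    seed = 14))
  art <- ds$truth$artifacts
  ev <- ds$evidence
  v <- ds$variants
  rows <- ev[paste(ev$site_id, ev$id) %in% paste(art$site_id, art$proband), ]
  j <- match(rows$site_id, v$site_id)
  fo <- foxog_metric(v$ref[j], v$alt[j], rows$f1r2_alt, rows$f2r1_alt)
  nonzero <- rows$alt_reads > 0
  # oxoG artifacts skew to the artifact orientation
  expect_gt(mean(fo[nonzero]), 0.85)
  # low allelic balance mostly fails the 0.15 proband bound
  ab <- allelic_balance(rows$ref_reads, rows$alt_reads)
  expect_gt(mean(ab < 0.35, na.rm = TRUE), 0.8)
  # an ordinary het C>A site has balanced orientation
  ds2 <- simulate_dataset(sim_config(n_families = 30, artifact_rate = 0,
                                     seed = 15))
  v2 <- ds2$variants
  ca <- v2$site_id[(v2$ref == "C" & v2$alt == "A") |
                     (v2$ref == "G" & v2$alt == "T")]
  tr2 <- ds2$truth$dnms
  ev2 <- ds2$evidence
  hets <- ev2[ev2$site_id %in% ca &
                paste(ev2$site_id, ev2$id) %in%
                  paste(tr2$site_id, tr2$proband), ]
  j2 <- match(hets$site_id, v2$site_id)
  fo2 <- foxog_metric(v2$ref[j2], v2$alt[j2], hets$f1r2_alt, hets$f2r1_alt)
  expect_lt(abs(mean(fo2) - 0.5), 0.1)
})

test_that("mendelian consistency holds without planted events", {
  # with no DNMs or artifacts the variant set is empty, so no trio site
  # can violate inheritance
  ds <- simulate_dataset(sim_config(n_families = 8, dnm_rate = 0,
                                    artifact_rate = 0, seed = 19))
  expect_identical(nrow(ds$variants), 0L)
  expect_identical(nrow(extract_candidates(ds)), 0L)
})

test_that("truth row counts match the planted events", {
  ds <- simulate_dataset(sim_config(n_families = 12, seed = 22))
  expect_identical(nrow(ds$truth$dnms) + nrow(ds$truth$artifacts),
                   nrow(ds$variants))
  expect_true(all(ds$truth$dnms$origin %in% c("paternal", "maternal")))
  # paternal fraction is near the configured 0.75
  p <- mean(ds$truth$dnms$origin == "paternal")
  n <- nrow(ds$truth$dnms)
  expect_lt(abs(p - 0.75), 3 * sqrt(0.75 * 0.25 / n))
})

test_that("end-to-end paternal fraction is recovered from phased DNMs", {
  sim <- cohort_sim()
  ph <- sim$res$phases
  tr <- sim$ds$truth$dnms
  j <- match(paste(ph$proband, ph$site_id), paste(tr$proband, tr$site_id))
  phased <- ph$origin %in% c("paternal", "maternal") & !is.na(j)
  n <- sum(phased)
  expect_gt(n, 500)
  est <- mean(ph$origin[phased] == "paternal")
  p0 <- sim$ds$sim$paternal_fraction
  expect_lt(abs(est - p0), 3 * sqrt(p0 * (1 - p0) / n))
})
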