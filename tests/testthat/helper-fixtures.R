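# shared fixtures: hand-built evidence rows, toy pedigrees, randomized
# trio datasets, and memoized simulations reused across test files

ev_row <- function(site, id, gt = "het", ref = 15L, alt = 15L,
                   depth = ref + alt, gq = 99L, f1r2 = NULL, f2r1 = NULL,
                   scf = 0.02, nf = 0.001) {
  if (is.null(f1r2)) f1r2 <- as.integer(floor(alt / 2))
  if (is.null(f2r1)) f2r1 <- as.integer(alt - f1r2)
  data.frame(site_id = site, id = id, gt = gt,
             ref_reads = as.integer(ref), alt_reads = as.integer(alt),
             depth = as.integer(depth), gq = as.integer(gq),
             f1r2_alt = f1r2, f2r1_alt = f2r1,
             softclip_frac = scf, n_frac = nf, stringsAsFactors = FALSE)
}

site_row <- function(site, chrom = "chr1", pos = 1000L, ref = "A",
                     alt = "G", gatk = TRUE) {
  data.frame(site_id = site, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, gatk_pass = gatk, is_snp = TRUE,
             multiallelic = FALSE, stringsAsFactors = FALSE)
}

trio_ped <- function(proband_sex = "female") {
  build_pedigree(data.frame(
    id = c("F", "M", "P"), sex = c("male", "female", proband_sex),
    father = c(NA, NA, "F"), mother = c(NA, NA, "M"),
    stringsAsFactors = FALSE))
}

default_samples <- function(ids, coverage = 34) {
  data.frame(id = ids, mean_coverage = coverage, mean_softclip = 0.03,
             mean_nfrac = 0.002, stringsAsFactors = FALSE)
}

trio_dataset <- function(variants, evidence, ped = trio_ped(), ...) {
  dnm_dataset(variants = variants, evidence = evidence, pedigree = ped,
              samples = default_samples(ped$records$id), ...)
}

# randomized trio cohort with outside carriers, couple descendants,
# X sites and occasional missing parental evidence — for the filter oracle.
# Each trio carries private candidate sites; unrelated pool individuals
# contribute outside-carrier evidence at a Poisson rate, occasionally
# exceeding the carrier bounds.
random_trio_dataset <- function(n_trios, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (t in seq_len(n_trios)) {
    pre <- sprintf("T%04d", t)
    psex <- sample(c("male", "female"), 1)
    rows[[length(rows) + 1L]] <- data.frame(
      id = paste0(pre, c("_f", "_m", "_p", "_c")),
      sex = c("male", "female", psex,
              sample(c("male", "female"), 1)),
      father = c(NA, NA, paste0(pre, "_f"),
                 if (psex == "male") paste0(pre, "_p") else paste0(pre, "_x")),
      mother = c(NA, NA, paste0(pre, "_m"),
                 if (psex == "female") paste0(pre, "_p") else paste0(pre, "_x")),
      stringsAsFactors = FALSE)
  }
  # grandchild parent placeholders and an unrelated carrier pool
  extra_ids <- unique(unlist(lapply(rows, function(r)
    setdiff(c(r$father, r$mother), c(r$id, NA)))))
  pool <- sprintf("U%03d", 1:20)
  recs <- rbind(do.call(rbind, rows),
                data.frame(id = extra_ids,
                           sex = ifelse(grepl("_x$", extra_ids), "female",
                                        "male"),
                           father = NA, mother = NA,
                           stringsAsFactors = FALSE),
                data.frame(id = pool, sex = "male", father = NA, mother = NA,
                           stringsAsFactors = FALSE))
  # fix placeholder sexes to match their role
  for (r in rows) {
    for (i in seq_len(nrow(r))) {
      fa <- r$father[i]; mo <- r$mother[i]
      if (!is.na(fa) && fa %in% recs$id) recs$sex[recs$id == fa] <- "male"
      if (!is.na(mo) && mo %in% recs$id) recs$sex[recs$id == mo] <- "female"
    }
  }
  ped <- build_pedigree(recs)
  ev <- list()
  # genotype-aware draws, with a fraction of fully random boundary
  # stressors so every rule sees values on both sides of its bound
  rnd_ev <- function(site, id, role = "other") {
    depth <- sample(c(0, 5, 8, 11, 12, 13, 20, 30, 40), 1,
                    prob = c(.02, .05, .05, .08, .1, .1, .2, .3, .1))
    if (runif(1) < 0.25) {   # stressor: arbitrary read mix
      alt <- if (depth == 0) 0L else sample(0:depth, 1)
      g <- sample(c("hom_ref", "het", "hom_alt", "missing"), 1,
                  prob = c(.3, .45, .15, .1))
    } else if (role == "parent") {
      g <- "hom_ref"
      alt <- if (depth == 0) 0L else rbinom(1, depth, 0.04)
    } else {
      g <- sample(c("hom_ref", "het", "hom_alt"), 1, prob = c(.3, .55, .15))
      p_alt <- switch(g, hom_ref = 0.02, het = 0.5, hom_alt = 0.97)
      alt <- if (depth == 0) 0L else rbinom(1, depth, p_alt)
    }
    ev_row(site, id, gt = g, ref = depth - alt, alt = alt, depth = depth,
           gq = sample(c(0:30, 99), 1),
           scf = round(sample(c(runif(1, 0, 0.09), runif(1, 0.08, 0.2)),
                              1, prob = c(.8, .2)), 3))
  }
  vars <- list()
  for (t in seq_len(n_trios)) {
    pre <- sprintf("T%04d", t)
    n_s <- sample(1:3, 1)
    for (k in seq_len(n_s)) {
      s <- sprintf("%s_s%d", pre, k)
      ref <- sample(c("A", "C", "G", "T"), 1)
      vars[[length(vars) + 1L]] <- site_row(
        s, chrom = sample(c("chr1", "chr2", "X"), 1, prob = c(.4, .4, .2)),
        pos = length(vars) * 997L + 11L, ref = ref,
        alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
        gatk = runif(1) < 0.8)
      ev[[length(ev) + 1L]] <- rnd_ev(s, paste0(pre, "_p"))
      if (runif(1) < 0.9)
        ev[[length(ev) + 1L]] <- rnd_ev(s, paste0(pre, "_f"), "parent")
      if (runif(1) < 0.9)
        ev[[length(ev) + 1L]] <- rnd_ev(s, paste0(pre, "_m"), "parent")
      if (runif(1) < 0.4) ev[[length(ev) + 1L]] <- rnd_ev(s, paste0(pre, "_c"))
      # outside carriers from the unrelated pool; occasionally enough to
      # trip the possible-carrier bound
      n_out <- if (runif(1) < 0.03) sample(10:13, 1) else rpois(1, 1.2)
      for (u in sample(pool, min(n_out, length(pool))))
        ev[[length(ev) + 1L]] <- rnd_ev(s, u)
    }
  }
  variants <- do.call(rbind, vars)
  evidence <- do.call(rbind, ev)
  evidence <- evidence[!duplicated(paste(evidence$site_id, evidence$id)), ]
  samples <- default_samples(recs$id)
  # a few probands below the coverage bound
  low <- sample(grep("_p$", recs$id, value = TRUE), max(1, n_trios %/% 20))
  samples$mean_coverage[samples$id %in% low] <- 15
  dnm_dataset(variants = variants, evidence = evidence, pedigree = ped,
              samples = samples)
}

# memoized simulations shared across test files (one computation per run)
.sim_cache <- new.env(parent = emptyenv())

cohort_sim <- function() {
  if (is.null(.sim_cache$cohort)) {
    ds <- simulate_dataset(sim_config(n_families = 120, artifact_rate = 18,
                                      seed = 1))
    res <- suppressWarnings(run_pipeline(ds))
    .sim_cache$cohort <- list(ds = ds, res = res)
  }
  .sim_cache$cohort
}

twin_sim <- function() {
  if (is.null(.sim_cache$twins)) {
    .sim_cache$twins <- simulate_dataset(
      sim_config(n_families = 50, n_twin_pairs = 50, artifact_rate = 0,
                 seed = 2))
  }
  .sim_cache$twins
}
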