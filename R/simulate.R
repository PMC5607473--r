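#' Simulation configuration
#'
#' Parameters of the pedigree-sequencing simulator.  Defaults emulate the
#' data regime the pipeline assumes: deep (34x) short-read trio
#' sequencing of three-generation families on a toy genome of two 10 Mb
#' autosomes with a uniform 1 cM/Mb map and a phased marker grid.
#'
#' @param n_families number of three-generation families.
#' @param offspring_per_proband integer vector the per-proband offspring
#'   count is drawn from (uniformly).
#' @param n_twin_pairs number of probands given a monozygotic twin.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param cm_per_mb uniform recombination rate (cM per Mb).
#' @param marker_spacing phased-marker grid spacing in bp.
#' @param coverage mean sequencing depth (reads per site), default 34.
#' @param dnm_rate mean planted germline DNMs per gamete (the per-proband
#'   count is Poisson with mean \code{2 * dnm_rate}).
#' @param paternal_fraction probability a planted DNM arises in the
#'   paternal gamete (a simulator default for exercising phasing).
#' @param somatic_fraction probability a planted DNM is post-twinning
#'   (present in the proband, absent in the MZ co-twin).
#' @param artifact_rate mean planted artifact sites per proband.
#' @param artifact_ab_shape Beta(a, b) parameters of the artifact allelic
#'   balance (default mean 0.2).
#' @param oxog_fraction fraction of artifacts that are oxoG-type C>A/G>T
#'   with skewed read-pair orientation.
#' @param oxog_skew orientation skew of oxoG artifact alt reads (0.95
#'   means 95:5 toward the artifact-prone orientation).
#' @param artifact_nposs_mean mean number of unrelated individuals also
#'   showing an artifact site (Poisson).
#' @param seq_error per-base sequencing error rate.
#' @param tracing_error probability a read pair links the DNM allele to
#'   the wrong marker allele.
#' @param pair_mean_depth mean read pairs linking a DNM allele to each
#'   nearby heterozygous marker (Poisson).
#' @param gatk_pass_true,gatk_pass_artifact probability a true / artifact
#'   site passes the GATK filters.
#' @param n_bad_lanes,n_contaminated,n_bad_probands,n_sample_swaps
#'   planted QC failures (lane-metric violations, contaminated samples,
#'   probands with excess soft clipping / N fraction, parent-child sample
#'   swaps).
#' @param seed RNG seed (mandatory).
#' @return a named list of class \code{sim_config}.
#' @export
sim_config <- function(n_families = 20,
                       offspring_per_proband = c(2L, 3L),
                       n_twin_pairs = 2,
                       chrom_lengths = c(chr1 = 10e6, chr2 = 10e6),
                       cm_per_mb = 1,
                       marker_spacing = 2000,
                       coverage = 34,
                       dnm_rate = 4,
                       paternal_fraction = 0.75,
                       somatic_fraction = 0.03,
                       artifact_rate = 8,
                       artifact_ab_shape = c(2, 8),
                       oxog_fraction = 0.5,
                       oxog_skew = 0.95,
                       artifact_nposs_mean = 1,
                       seq_error = 0.002,
                       tracing_error = 0.005,
                       pair_mean_depth = 5,
                       gatk_pass_true = 0.98,
                       gatk_pass_artifact = 0.5,
                       n_bad_lanes = 0,
                       n_contaminated = 0,
                       n_bad_probands = 0,
                       n_sample_swaps = 0,
                       seed = 1L) {
  if (is.na(seed)) stop("a seed is mandatory")
  for (f in c("paternal_fraction", "somatic_fraction", "oxog_fraction",
              "oxog_skew", "seq_error", "tracing_error")) {
    v <- get(f)
    if (v < 0 || v > 1) stop("'", f, "' must be in [0, 1]")
  }
  structure(as.list(environment()), class = "sim_config")
}

sim_ids <- function(f, what, k = NULL) {
  base <- sprintf("F%03d", f)
  switch(what,
         gf = paste0(base, "_gf"), gm = paste0(base, "_gm"),
         p = paste0(base, "_p"), sp = paste0(base, "_sp"),
         tw = paste0(base, "_tw"),
         off = sprintf("%s_o%d", base, k))
}

#' Simulate a pedigree of three-generation families
#'
#' Each family has a founder couple, a proband (their child), an
#' unrelated spouse, and the proband's offspring; the first
#' \code{n_twin_pairs} probands get an MZ co-twin (same parents, same
#' sex, shared twin-group label).
#'
#' @param cfg a \code{sim_config}.
#' @return list with \code{pedigree} (a \code{dnm_pedigree}) and
#'   \code{n_offspring} (per-family offspring counts).  Uses the current
#'   RNG state; \code{\link{simulate_dataset}} seeds it from
#'   \code{cfg$seed}.
#' @export
simulate_pedigree <- function(cfg) {
  rows <- list()
  n_off <- integer(cfg$n_families)
  for (f in seq_len(cfg$n_families)) {
    gf <- sim_ids(f, "gf"); gm <- sim_ids(f, "gm")
    p <- sim_ids(f, "p"); sp <- sim_ids(f, "sp")
    psex <- sample(c("male", "female"), 1)
    spsex <- if (psex == "male") "female" else "male"
    k <- cfg$offspring_per_proband[
      sample.int(length(cfg$offspring_per_proband), 1)]
    n_off[f] <- k
    twin <- f <= cfg$n_twin_pairs
    rows[[f]] <- data.frame(
      id = c(gf, gm, p, if (twin) sim_ids(f, "tw"), sp,
             vapply(seq_len(k), function(i) sim_ids(f, "off", i), "")),
      sex = c("male", "female", psex, if (twin) psex, spsex,
              sample(c("male", "female"), k, replace = TRUE)),
      father = c(NA, NA, gf, if (twin) gf, NA,
                 rep(if (psex == "male") p else sp, k)),
      mother = c(NA, NA, gm, if (twin) gm, NA,
                 rep(if (psex == "female") p else sp, k)),
      twin_group = c(NA, NA, if (twin) rep(sprintf("TG%03d", f), 2) else NA,
                     NA, rep(NA, k)),
      stringsAsFactors = FALSE)
  }
  list(pedigree = build_pedigree(do.call(rbind, rows)), n_offspring = n_off)
}

sim_map <- function(cfg) {
  chroms <- names(cfg$chrom_lengths)
  marker_pos <- lapply(chroms, function(ch)
    seq(cfg$marker_spacing, cfg$chrom_lengths[[ch]], by = cfg$marker_spacing))
  names(marker_pos) <- chroms
  list(chroms = chroms, len_bp = cfg$chrom_lengths,
       cm_per_mb = cfg$cm_per_mb, marker_pos = marker_pos,
       marker_cm = lapply(marker_pos, function(p) p * cfg$cm_per_mb / 1e6),
       len_cm = cfg$chrom_lengths * cfg$cm_per_mb / 1e6)
}

# one meiosis: crossover breakpoints (Haldane: Poisson count, uniform in
# cM) and the starting parental haplotype per chromosome
sim_meiosis <- function(map) {
  lapply(stats::setNames(map$chroms, map$chroms), function(ch) {
    L <- map$len_cm[[ch]]
    k <- stats::rpois(1, L / 100)
    list(breaks = sort(stats::runif(k, 0, L)),
         start = sample(c("pat", "mat"), 1))
  })
}

# which parental haplotype a gamete carries at position cm
meiosis_source <- function(mei_chr, cm) {
  n <- findInterval(cm, mei_chr$breaks)
  flip <- n %% 2L == 1L
  ifelse(xor(mei_chr$start == "mat", flip), "mat", "pat")
}

# gamete alleles at the marker grid, given the parent's two haplotypes
gamete_alleles <- function(mei_chr, cm, pat_alleles, mat_alleles) {
  src <- meiosis_source(mei_chr, cm)
  ifelse(src == "pat", pat_alleles, mat_alleles)
}

# the crossover-bounded segment of a gamete containing position cm
meiosis_segment <- function(mei_chr, cm, L, marker_cm) {
  bounds <- c(0, mei_chr$breaks, L)
  i <- findInterval(cm, bounds)
  lo <- bounds[i]; hi <- bounds[i + 1L]
  list(start_cm = lo, end_cm = hi, length_cm = hi - lo,
       n_markers = sum(marker_cm > lo & marker_cm <= hi))
}

#' Simulate a complete dataset with known truth
#'
#' Generates a pedigree, recombinant haplotypes over the toy genome,
#' planted germline DNMs (with parent of origin and post-twinning
#' status), artifact sites with skewed allelic balance and oxoG
#' orientation bias, per-site read evidence, read-pair linkage counts,
#' phased-marker tables, per-offspring inheritance (which proband
#' haplotype each offspring carries at each candidate site, with the
#' crossover-bounded segment), lane metrics, contamination surrogates and
#' parent-child IBD summaries — everything \code{\link{run_pipeline}}
#' consumes, plus truth tables.
#'
#' @param cfg a \code{sim_config}.
#' @return a \code{dnm_dataset}; its \code{truth} element holds the
#'   planted DNMs (\code{dnms}), artifacts (\code{artifacts}), sample
#'   swaps, bad lanes and bad probands.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  map <- sim_map(cfg)
  pedres <- simulate_pedigree(cfg)
  ped <- pedres$pedigree
  recs <- ped$records
  founders <- recs$id[is.na(recs$father) & is.na(recs$mother)]

  # founder marker haplotypes: allele states 1/2, frequency 0.5
  hap <- list()
  for (id in founders)
    hap[[id]] <- lapply(map$marker_pos, function(p)
      list(pat = sample(1:2, length(p), TRUE),
           mat = sample(1:2, length(p), TRUE)))

  fams <- list()
  for (f in seq_len(cfg$n_families)) {
    p <- sim_ids(f, "p"); gf <- sim_ids(f, "gf"); gm <- sim_ids(f, "gm")
    k <- pedres$n_offspring[f]
    off <- vapply(seq_len(k), function(i) sim_ids(f, "off", i), "")
    twin <- if (f <= cfg$n_twin_pairs) sim_ids(f, "tw") else NA_character_
    # proband haplotypes from one meiosis of each founder
    mei_gf <- sim_meiosis(map); mei_gm <- sim_meiosis(map)
    hap[[p]] <- lapply(stats::setNames(map$chroms, map$chroms), function(ch)
      list(pat = gamete_alleles(mei_gf[[ch]], map$marker_cm[[ch]],
                                hap[[gf]][[ch]]$pat, hap[[gf]][[ch]]$mat),
           mat = gamete_alleles(mei_gm[[ch]], map$marker_cm[[ch]],
                                hap[[gm]][[ch]]$pat, hap[[gm]][[ch]]$mat)))
    # the MZ twin shares the proband's pre-twinning genome
    if (!is.na(twin)) hap[[twin]] <- hap[[p]]
    # proband -> offspring meioses (structure only)
    mei_off <- lapply(off, function(o) sim_meiosis(map))
    names(mei_off) <- off
    fams[[f]] <- list(f = f, proband = p, father = gf, mother = gm,
                      offspring = off, twin = twin, mei_off = mei_off)
  }

  # ---- plant DNMs and artifacts -------------------------------------
  all_probands <- vapply(fams, `[[`, "", "proband")
  sites <- list(); plant <- list()
  genome_len <- sum(map$len_bp)
  draw_pos <- function(n) {
    ch <- sample(map$chroms, n, replace = TRUE,
                 prob = map$len_bp / genome_len)
    pos <- vapply(ch, function(c0)
      sample.int(map$len_bp[[c0]] - 1L, 1L), 1L)
    pos <- pos + (pos %% cfg$marker_spacing == 0L)  # stay off the grid
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  for (fam in fams) {
    p <- fam$proband
    n_dnm <- stats::rpois(1, 2 * cfg$dnm_rate)
    if (n_dnm > 0) {
      loc <- draw_pos(n_dnm)
      ref <- sample(bases, n_dnm, TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
      origin <- ifelse(stats::runif(n_dnm) < cfg$paternal_fraction,
                       "paternal", "maternal")
      post <- stats::runif(n_dnm) < cfg$somatic_fraction
      plant[[length(plant) + 1L]] <- data.frame(
        chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
        proband = p, kind = "dnm", origin = origin, post_twinning = post,
        oxog = FALSE, stringsAsFactors = FALSE)
    }
    # the MZ co-twin gets its own private post-twinning DNMs at the same
    # per-genome rate, so discordance is symmetric between the twins
    if (!is.na(fam$twin)) {
      n_som <- stats::rpois(1, 2 * cfg$dnm_rate * cfg$somatic_fraction)
      if (n_som > 0) {
        loc <- draw_pos(n_som)
        ref <- sample(bases, n_som, TRUE)
        alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
        plant[[length(plant) + 1L]] <- data.frame(
          chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
          proband = fam$twin, kind = "dnm",
          origin = ifelse(stats::runif(n_som) < cfg$paternal_fraction,
                          "paternal", "maternal"),
          post_twinning = TRUE, oxog = FALSE, stringsAsFactors = FALSE)
      }
    }
    n_art <- stats::rpois(1, cfg$artifact_rate)
    if (n_art > 0) {
      loc <- draw_pos(n_art)
      is_ox <- stats::runif(n_art) < cfg$oxog_fraction
      ref <- alt <- character(n_art)
      for (i in seq_len(n_art)) {
        if (is_ox[i]) {
          if (stats::runif(1) < 0.5) { ref[i] <- "C"; alt[i] <- "A" }
          else { ref[i] <- "G"; alt[i] <- "T" }
        } else {
          ref[i] <- sample(bases, 1)
          alt[i] <- sample(setdiff(bases, ref[i]), 1)
        }
      }
      plant[[length(plant) + 1L]] <- data.frame(
        chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
        proband = p, kind = "artifact", origin = NA_character_,
        post_twinning = FALSE, oxog = is_ox, stringsAsFactors = FALSE)
    }
  }
  plant <- if (length(plant)) do.call(rbind, plant) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), proband = character(0),
               kind = character(0), origin = character(0),
               post_twinning = logical(0), oxog = logical(0),
               stringsAsFactors = FALSE)
  # unique positions
  while (anyDuplicated(paste(plant$chrom, plant$pos))) {
    d <- duplicated(paste(plant$chrom, plant$pos))
    loc <- draw_pos(sum(d))
    plant$chrom[d] <- loc$chrom; plant$pos[d] <- loc$pos
  }
  ord <- order(plant$chrom, plant$pos)
  plant <- plant[ord, , drop = FALSE]
  plant$site_id <- sprintf("s%05d", seq_len(nrow(plant)))
  plant$gatk_pass <- stats::runif(nrow(plant)) <
    ifelse(plant$kind == "dnm", cfg$gatk_pass_true, cfg$gatk_pass_artifact)

  variants <- data.frame(
    site_id = plant$site_id, chrom = plant$chrom, pos = plant$pos,
    ref = plant$ref, alt = plant$alt, gatk_pass = plant$gatk_pass,
    is_snp = rep(TRUE, nrow(plant)),
    multiallelic = rep(FALSE, nrow(plant)), stringsAsFactors = FALSE)

  fam_of <- stats::setNames(fams, all_probands)
  for (fam in fams) if (!is.na(fam$twin)) fam_of[[fam$twin]] <- fam

  # ---- evidence plan -------------------------------------------------
  plan <- list()
  add <- function(site, id, kind, oxog_orient) {
    plan[[length(plan) + 1L]] <<- data.frame(
      site_id = site, id = id, kind = kind, oxog_orient = oxog_orient,
      stringsAsFactors = FALSE)
  }
  outside_pool <- recs$id
  inherit_rows <- list()
  for (i in seq_len(nrow(plant))) {
    s <- plant[i, ]
    fam <- fam_of[[s$proband]]
    orient <- if (!s$oxog) "balanced" else
      if (s$ref == "C") "f2r1" else "f1r2"
    cmpos <- s$pos * cfg$cm_per_mb / 1e6
    if (s$kind == "dnm") {
      carrier_is_twin <- !is.na(fam$twin) && s$proband == fam$twin
      co <- if (is.na(fam$twin)) NA_character_ else
        if (carrier_is_twin) fam$proband else fam$twin
      add(s$site_id, s$proband, "het", "balanced")
      add(s$site_id, fam$father, "homref", "balanced")
      add(s$site_id, fam$mother, "homref", "balanced")
      if (!is.na(co))
        add(s$site_id, co,
            if (s$post_twinning) "homref" else "het", "balanced")
      for (o in fam$offspring) {
        if (carrier_is_twin) {   # the twin has no offspring in the family
          add(s$site_id, o, "homref", "balanced")
          next
        }
        src <- meiosis_source(fam$mei_off[[o]][[s$chrom]], cmpos)
        carried <- (src == "pat") == (s$origin == "paternal")
        add(s$site_id, o, if (carried) "het" else "homref", "balanced")
      }
    } else {
      add(s$site_id, s$proband, "artifact", orient)
      add(s$site_id, fam$father, "homref", "balanced")
      add(s$site_id, fam$mother, "homref", "balanced")
      if (!is.na(fam$twin)) add(s$site_id, fam$twin, "homref", "balanced")
      for (o in fam$offspring) add(s$site_id, o, "homref", "balanced")
      n_out <- stats::rpois(1, cfg$artifact_nposs_mean)
      if (n_out > 0) {
        fam_ids <- c(fam$proband, fam$father, fam$mother, fam$twin,
                     fam$offspring)
        pool <- setdiff(outside_pool, fam_ids)
        for (o in sample(pool, min(n_out, length(pool))))
          add(s$site_id, o, "artifact", orient)
      }
    }
    # inheritance (positional, for every offspring of the site's proband)
    for (o in fam$offspring) {
      mei <- fam$mei_off[[o]][[s$chrom]]
      src <- meiosis_source(mei, cmpos)
      seg <- meiosis_segment(mei, cmpos, map$len_cm[[s$chrom]],
                             map$marker_cm[[s$chrom]])
      inherit_rows[[length(inherit_rows) + 1L]] <- data.frame(
        offspring = o, site_id = s$site_id,
        proband_hap = if (src == "pat") "paternal" else "maternal",
        seg_cm = seg$length_cm, seg_markers = seg$n_markers,
        stringsAsFactors = FALSE)
    }
  }
  plan <- if (length(plan)) do.call(rbind, plan) else
    data.frame(site_id = character(0), id = character(0),
               kind = character(0), oxog_orient = character(0),
               stringsAsFactors = FALSE)
  inheritance <- if (length(inherit_rows)) do.call(rbind, inherit_rows) else
    data.frame(offspring = character(0), site_id = character(0),
               proband_hap = character(0), seg_cm = numeric(0),
               seg_markers = integer(0), stringsAsFactors = FALSE)

  evidence <- sim_reads(plan, cfg)

  # ---- marker phase and read-pair counts -----------------------------
  mp_rows <- list(); pc_rows <- list()
  dnms <- plant[plant$kind == "dnm", , drop = FALSE]
  for (i in seq_len(nrow(dnms))) {
    s <- dnms[i, ]
    p <- s$proband
    mpos <- map$marker_pos[[s$chrom]]
    near <- which(abs(mpos - s$pos) <= pair_window_internal(cfg))
    if (!length(near)) next
    pa <- hap[[p]][[s$chrom]]$pat[near]
    ma <- hap[[p]][[s$chrom]]$mat[near]
    het <- pa != ma
    if (!any(het)) next
    for (j in which(het)) {
      mk <- sprintf("m_%s_%d", s$chrom, mpos[near[j]])
      mp_rows[[length(mp_rows) + 1L]] <- data.frame(
        id = p, marker_site = mk, marker_chrom = s$chrom,
        marker_pos = mpos[near[j]], paternal_allele = pa[j],
        stringsAsFactors = FALSE)
      # read pairs: alt allele sits on the origin haplotype
      origin_allele <- if (s$origin == "paternal") pa[j] else ma[j]
      other_allele <- 3L - origin_allele  # marker is heterozygous
      n_alt <- stats::rpois(1, cfg$pair_mean_depth)
      n_ref <- stats::rpois(1, cfg$pair_mean_depth)
      flip_a <- stats::rbinom(1, n_alt, cfg$tracing_error)
      flip_r <- stats::rbinom(1, n_ref, cfg$tracing_error)
      cnt <- c(a1 = 0L, a2 = 0L, r1 = 0L, r2 = 0L)
      cnt[paste0("a", origin_allele)] <- n_alt - flip_a
      cnt[paste0("a", 3L - origin_allele)] <- flip_a
      cnt[paste0("r", other_allele)] <- n_ref - flip_r
      cnt[paste0("r", 3L - other_allele)] <- flip_r
      pc_rows[[length(pc_rows) + 1L]] <- data.frame(
        proband = p, dnm_site = s$site_id, marker_site = mk,
        n_ref_allele1 = cnt[["r1"]], n_ref_allele2 = cnt[["r2"]],
        n_alt_allele1 = cnt[["a1"]], n_alt_allele2 = cnt[["a2"]],
        n_multi = stats::rpois(1, 0.05), stringsAsFactors = FALSE)
    }
  }
  marker_phase <- if (length(mp_rows)) unique(do.call(rbind, mp_rows)) else
    data.frame(id = character(0), marker_site = character(0),
               marker_chrom = character(0), marker_pos = integer(0),
               paternal_allele = integer(0), stringsAsFactors = FALSE)
  pair_counts <- if (length(pc_rows)) do.call(rbind, pc_rows) else
    data.frame(proband = character(0), dnm_site = character(0),
               marker_site = character(0), n_ref_allele1 = integer(0),
               n_ref_allele2 = integer(0), n_alt_allele1 = integer(0),
               n_alt_allele2 = integer(0), n_multi = integer(0),
               stringsAsFactors = FALSE)

  # ---- samples, lanes, contamination, IBD ----------------------------
  n_ind <- nrow(recs)
  samples <- data.frame(
    id = recs$id,
    mean_coverage = cfg$coverage,
    mean_softclip = round(stats::runif(n_ind, 0.01, 0.05), 4),
    mean_nfrac = round(stats::runif(n_ind, 0.001, 0.005), 4),
    stringsAsFactors = FALSE)
  bad_probands <- character(0)
  if (cfg$n_bad_probands > 0) {
    bad_probands <- sample(all_probands,
                           min(cfg$n_bad_probands, length(all_probands)))
    j <- match(bad_probands, samples$id)
    which_rule <- sample(c("softclip", "nfrac"), length(j), TRUE)
    samples$mean_softclip[j] <- ifelse(which_rule == "softclip",
      round(stats::runif(length(j), 0.12, 0.2), 4), samples$mean_softclip[j])
    samples$mean_nfrac[j] <- ifelse(which_rule == "nfrac",
      round(stats::runif(length(j), 0.02, 0.03), 4), samples$mean_nfrac[j])
  }
  lane_metrics <- data.frame(
    lane_id = paste0("L_", recs$id), sample_id = recs$id,
    mean_base_quality = round(stats::rnorm(n_ind, 35, 1), 2),
    pct_duplicates = round(stats::runif(n_ind, 5, 20), 2),
    mean_n_per_read = round(stats::runif(n_ind, 0, 5), 2),
    pct_mapq_lt20 = round(stats::runif(n_ind, 1, 8), 2),
    pct_unmapped = round(stats::runif(n_ind, 0.5, 5), 2),
    pct_both_unmapped = round(stats::runif(n_ind, 0.1, 2), 2),
    pct_first_unmapped = round(stats::runif(n_ind, 0.1, 3), 2),
    pct_second_unmapped = round(stats::runif(n_ind, 0.1, 3), 2),
    chip_mismatch_rate = round(stats::runif(n_ind, 0, 0.005), 5),
    stringsAsFactors = FALSE)
  bad_lanes <- character(0)
  if (cfg$n_bad_lanes > 0) {
    j <- sample(n_ind, min(cfg$n_bad_lanes, n_ind))
    bad_lanes <- lane_metrics$lane_id[j]
    fields <- sample(c("mean_base_quality", "pct_duplicates",
                       "chip_mismatch_rate"), length(j), TRUE)
    for (k in seq_along(j)) {
      lane_metrics[[fields[k]]][j[k]] <- switch(fields[k],
        mean_base_quality = round(stats::runif(1, 15, 24.9), 2),
        pct_duplicates = round(stats::runif(1, 51, 80), 2),
        chip_mismatch_rate = round(stats::runif(1, 0.021, 0.1), 5))
    }
  }
  het_pair_support <- data.frame(
    sample_id = recs$id, n_snp_pairs = 50000L,
    n_pairs_third_hap_ge2 = stats::rbinom(n_ind, 50000L, 2e-4),
    stringsAsFactors = FALSE)
  contaminated <- character(0)
  if (cfg$n_contaminated > 0) {
    j <- sample(n_ind, min(cfg$n_contaminated, n_ind))
    contaminated <- recs$id[j]
    het_pair_support$n_pairs_third_hap_ge2[j] <-
      stats::rbinom(length(j), 50000L, 0.003)
  }
  pc_links <- list()
  for (i in seq_len(n_ind)) {
    for (par in c(recs$father[i], recs$mother[i])) {
      if (!is.na(par) && par %in% recs$id)
        pc_links[[length(pc_links) + 1L]] <- c(par, recs$id[i])
    }
  }
  ibd <- data.frame(
    id1 = vapply(pc_links, `[[`, "", 1L),
    id2 = vapply(pc_links, `[[`, "", 2L),
    shared_fraction = round(stats::runif(length(pc_links), 0.97, 1), 4),
    stringsAsFactors = FALSE)
  swapped <- data.frame(id1 = character(0), id2 = character(0),
                        stringsAsFactors = FALSE)
  if (cfg$n_sample_swaps > 0 && nrow(ibd)) {
    j <- sample(nrow(ibd), min(cfg$n_sample_swaps, nrow(ibd)))
    ibd$shared_fraction[j] <- round(stats::runif(length(j), 0, 0.05), 4)
    swapped <- ibd[j, c("id1", "id2")]
  }

  genetic_map <- do.call(rbind, lapply(map$chroms, function(ch)
    data.frame(chrom = ch, pos = map$marker_pos[[ch]],
               cM = map$marker_cm[[ch]], stringsAsFactors = FALSE)))

  truth <- list(
    dnms = data.frame(site_id = dnms$site_id, chrom = dnms$chrom,
                      pos = dnms$pos, proband = dnms$proband,
                      origin = dnms$origin,
                      post_twinning = dnms$post_twinning,
                      stringsAsFactors = FALSE),
    artifacts = plant[plant$kind == "artifact",
                      c("site_id", "chrom", "pos", "proband", "oxog")],
    swapped_pairs = swapped, bad_lanes = bad_lanes,
    bad_probands = bad_probands, contaminated = contaminated)
  rownames(truth$artifacts) <- NULL

  new_dataset(variants = variants, evidence = evidence, pedigree = ped,
              samples = samples, genetic_map = genetic_map,
              marker_phase = marker_phase, pair_counts = pair_counts,
              lane_metrics = lane_metrics,
              het_pair_support = het_pair_support, ibd_pairs = ibd,
              inheritance = inheritance, truth = truth, sim = cfg)
}

# window used when choosing markers to emit linkage for; matches the
# pipeline's default pairing window (run_config()$pair_window)
pair_window_internal <- function(cfg) 5000

# read-level evidence for a plan of (site, individual, genotype kind)
sim_reads <- function(plan, cfg) {
  n <- nrow(plan)
  if (!n)
    return(data.frame(site_id = character(0), id = character(0),
                      gt = character(0), ref_reads = integer(0),
                      alt_reads = integer(0), depth = integer(0),
                      gq = integer(0), f1r2_alt = integer(0),
                      f2r1_alt = integer(0), softclip_frac = numeric(0),
                      n_frac = numeric(0), stringsAsFactors = FALSE))
  depth <- stats::rpois(n, cfg$coverage)
  ab_true <- numeric(n)
  ab_true[plan$kind == "homref"] <- cfg$seq_error / 3
  ab_true[plan$kind == "het"] <- 0.5
  ab_true[plan$kind == "homalt"] <- 1 - cfg$seq_error / 3
  art <- plan$kind == "artifact"
  ab_true[art] <- stats::rbeta(sum(art), cfg$artifact_ab_shape[1],
                               cfg$artifact_ab_shape[2])
  alt <- stats::rbinom(n, depth, ab_true)
  ref <- depth - alt
  # maximum-likelihood genotype call and quality from the read counts
  e <- 0.01
  ll <- cbind(hom_ref = alt * log(e / 3) + ref * log(1 - e),
              het = (ref + alt) * log(0.5),
              hom_alt = ref * log(e / 3) + alt * log(1 - e))
  best <- max.col(ll)
  gt <- colnames(ll)[best]
  sec <- apply(ll, 1, function(r) sort(r, decreasing = TRUE)[2])
  gq <- pmin(99L, as.integer(round((ll[cbind(seq_len(n), best)] - sec) *
                                     10 / log(10))))
  gt[depth == 0L] <- "missing"
  gq[depth == 0L] <- 0L
  # orientation split of the alt reads
  p_f1r2 <- ifelse(plan$oxog_orient == "f1r2", cfg$oxog_skew,
                   ifelse(plan$oxog_orient == "f2r1", 1 - cfg$oxog_skew, 0.5))
  f1r2 <- stats::rbinom(n, alt, p_f1r2)
  data.frame(
    site_id = plan$site_id, id = plan$id, gt = gt,
    ref_reads = ref, alt_reads = alt, depth = depth, gq = gq,
    f1r2_alt = f1r2, f2r1_alt = alt - f1r2,
    softclip_frac = round(stats::rbeta(n, 2, 50), 4),
    n_frac = round(stats::rbeta(n, 2, 400), 4),
    stringsAsFactors = FALSE)
}
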