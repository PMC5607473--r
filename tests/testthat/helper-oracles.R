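# independent brute-force oracles, deliberately written as plain
# rule-by-rule / enumeration logic (only the table lookups are indexed,
# the decisions themselves are spelled out)

oracle_descendants <- function(ped, father, mother) {
  recs <- ped$records
  fa <- stats::setNames(recs$father, recs$id)
  mo <- stats::setNames(recs$mother, recs$id)
  anc_or_self <- function(id) {
    out <- id
    repeat {
      more <- unique(c(fa[out], mo[out]))
      more <- more[!is.na(more) & more %in% recs$id]
      if (all(more %in% out)) return(out)
      out <- unique(c(out, more))
    }
  }
  hit <- vapply(recs$id, function(x)
    any(vapply(anc_or_self(x), function(a)
      identical(unname(fa[a]), father) && identical(unname(mo[a]), mother),
      TRUE)), TRUE)
  sort(recs$id[hit])
}

# rule-by-rule candidate filter, one explicit test per printed criterion
oracle_extract <- function(ds, config = run_config()) {
  recs <- ds$pedigree$records
  ev <- ds$evidence
  row_of <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(ev)))
    assign(paste(ev$site_id[i], ev$id[i]), i, envir = row_of)
  get_ev <- function(site, id) {
    i <- mget(paste(site, id), envir = row_of, ifnotfound = list(NULL))[[1]]
    if (is.null(i)) NULL else ev[i, ]
  }
  ev_at_site <- split(seq_len(nrow(ev)), ev$site_id)
  # ancestor-or-self sets, computed once; descendant-of-couple = anyone
  # whose set contains a child of exactly that couple
  fa_vec <- stats::setNames(recs$father, recs$id)
  mo_vec <- stats::setNames(recs$mother, recs$id)
  ancsets <- stats::setNames(vector("list", nrow(recs)), recs$id)
  for (id in recs$id) {
    out <- id
    repeat {
      more <- unique(c(fa_vec[out], mo_vec[out]))
      more <- more[!is.na(more) & more %in% recs$id]
      if (all(more %in% out)) break
      out <- unique(c(out, more))
    }
    ancsets[[id]] <- out
  }
  desc_map <- new.env(parent = emptyenv())
  for (x in recs$id) {
    keys <- unique(paste(fa_vec[ancsets[[x]]], mo_vec[ancsets[[x]]]))
    for (k in keys)
      desc_map[[k]] <- c(desc_map[[k]], x)
  }
  descendants <- function(fa, mo) {
    d <- desc_map[[paste(fa, mo)]]
    if (is.null(d)) character(0) else sort(d)
  }
  sites_of <- split(ev$site_id, ev$id)
  var_row <- stats::setNames(seq_len(nrow(ds$variants)),
                             ds$variants$site_id)
  found <- list()
  for (i in seq_len(nrow(recs))) {
    pid <- recs$id[i]; fa <- recs$father[i]; mo <- recs$mother[i]
    if (is.na(fa) || is.na(mo) || !(fa %in% recs$id) || !(mo %in% recs$id))
      next
    cov <- ds$samples$mean_coverage[ds$samples$id == pid]
    if (length(cov) == 0 || is.na(cov) || !(cov > config$min_proband_coverage))
      next
    male_p <- recs$sex[i] == "male"
    excl <- descendants(fa, mo)
    for (s in var_row[unique(sites_of[[pid]])]) {
      v <- ds$variants[s, ]
      p <- get_ev(v$site_id, pid)
      if (is.null(p)) next
      if (!(p$gt %in% c("het", "hom_alt"))) next
      fe <- get_ev(v$site_id, fa); me <- get_ev(v$site_id, mo)
      if (is.null(fe) || is.null(me)) next
      if (p$ref_reads + p$alt_reads == 0) next
      pab <- p$alt_reads / (p$ref_reads + p$alt_reads)
      x_male <- v$chrom %in% c("X", "chrX") && male_p
      ok <- TRUE
      if ((p$gt == "hom_alt" || x_male) &&
          p$ref_reads > config$max_homalt_ref_reads) ok <- FALSE
      if (p$depth < config$min_proband_depth) ok <- FALSE
      if (pab < config$min_proband_ab) ok <- FALSE
      fmin <- if (x_male) config$min_parent_depth_x_father else
        config$min_parent_depth
      if (fe$depth < fmin) ok <- FALSE
      if (me$depth < config$min_parent_depth) ok <- FALSE
      if (fe$alt_reads > config$max_parent_alt) ok <- FALSE
      if (me$alt_reads > config$max_parent_alt) ok <- FALSE
      if (fe$ref_reads + fe$alt_reads > 0 &&
          fe$alt_reads / (fe$ref_reads + fe$alt_reads) > config$max_parent_ab)
        ok <- FALSE
      if (me$ref_reads + me$alt_reads > 0 &&
          me$alt_reads / (me$ref_reads + me$alt_reads) > config$max_parent_ab)
        ok <- FALSE
      if (p$softclip_frac > config$max_site_softclip) ok <- FALSE
      # carrier counts by direct loop over the site's evidence
      np <- 0L; nl <- 0L
      for (j in ev_at_site[[v$site_id]]) {
        o <- ev[j, ]
        if (o$id %in% excl) next
        if (!(o$gt %in% c("het", "hom_alt"))) next
        np <- np + 1L
        if (o$ref_reads + o$alt_reads > 0) {
          oab <- o$alt_reads / (o$ref_reads + o$alt_reads)
          if (o$depth > config$likely_min_depth &&
              abs(oab - 0.5) < config$likely_ab_dev &&
              o$gq > config$likely_min_gq) nl <- nl + 1L
        }
      }
      if (np > config$max_possible_carriers) ok <- FALSE
      if (nl > config$max_likely_carriers) ok <- FALSE
      if (ok)
        found[[length(found) + 1L]] <- data.frame(
          proband = pid, site_id = v$site_id,
          n_possible_outside = np, n_likely_outside = nl,
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(found)) do.call(rbind, found) else
    data.frame(proband = character(0), site_id = character(0),
               n_possible_outside = integer(0),
               n_likely_outside = integer(0), stringsAsFactors = FALSE)
  out[order(out$proband, out$site_id), , drop = FALSE]
}

# transmission label by exhaustive enumeration of the haplotype carrying
# the mutation
oracle_transmission <- function(offspring, x_site = FALSE,
                                config = run_config()) {
  stat <- rep(NA, nrow(offspring))
  for (i in seq_len(nrow(offspring))) {
    o <- offspring[i, ]
    if (is.na(o$gt) || o$gt == "missing" ||
        o$depth < config$offspring_min_depth) next
    carries <- o$gt %in% c("het", "hom_alt")
    if (carries) {
      tot <- o$ref_reads + o$alt_reads
      if (o$alt_reads < config$offspring_min_alt || tot == 0 ||
          o$alt_reads / tot < config$offspring_min_ab) next
    }
    stat[i] <- carries
  }
  inf <- which(!is.na(stat) & !is.na(offspring$hap))
  if (length(inf) < config$min_offspring ||
      length(unique(offspring$hap[inf])) < 2)
    return("unevaluable")
  if (x_site) {
    for (i in inf) {
      if (stat[i] && offspring$sex[i] == "male" &&
          offspring$gt[i] != "hom_alt") return("inconsistent")
    }
  }
  for (H in c("paternal", "maternal")) {
    all_ok <- TRUE
    for (i in inf) {
      on_H <- offspring$hap[i] == H
      if (on_H && !stat[i]) all_ok <- FALSE
      if (!on_H && stat[i]) all_ok <- FALSE
    }
    if (all_ok) return("consistent")
  }
  "inconsistent"
}

oracle_variant_summary_cell <- function(variants, type, allele, col,
                                        threshold = 0.8) {
  n <- 0L
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (type != "Total" && v$is_snp != (type == "SNP")) next
    if (v$multiallelic != (allele == "Non-biallelic")) next
    ok <- switch(col, total = TRUE, gatk_pass = isTRUE(v$gatk_pass),
                 phase_pass = !is.na(v$phase_score) &&
                   v$phase_score > threshold,
                 imputation_pass = !is.na(v$impute_info) &&
                   v$impute_info > threshold)
    if (ok) n <- n + 1L
  }
  n
}
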