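#' Assemble a dataset from its component tables
#'
#' Builds the container the pipeline operates on.  Only \code{variants},
#' \code{evidence}, \code{pedigree} and \code{samples} are required;
#' every individual referenced by the evidence or sample tables must
#' exist in the pedigree, and genetic-map positions must be strictly
#' increasing in bp with non-decreasing cM per chromosome.
#'
#' @param variants data.frame: \code{site_id}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{gatk_pass}, \code{is_snp},
#'   \code{multiallelic}.
#' @param evidence data.frame of per-(individual, site) read summaries:
#'   \code{site_id}, \code{id}, \code{gt}, \code{ref_reads},
#'   \code{alt_reads}, \code{depth}, \code{gq}, \code{f1r2_alt},
#'   \code{f2r1_alt}, \code{softclip_frac}, \code{n_frac}.
#' @param pedigree a \code{dnm_pedigree}.
#' @param samples data.frame: \code{id}, \code{mean_coverage},
#'   \code{mean_softclip}, \code{mean_nfrac}.
#' @param genetic_map,marker_phase,pair_counts,lane_metrics,
#'   het_pair_support,ibd_pairs,inheritance optional auxiliary tables
#'   (see the corresponding pipeline stages for their schemas).
#' @param truth optional simulator truth list.
#' @param sim optional \code{sim_config} provenance.
#' @return a \code{dnm_dataset}.
#' @export
dnm_dataset <- function(variants, evidence, pedigree, samples,
                        genetic_map = NULL, marker_phase = NULL,
                        pair_counts = NULL, lane_metrics = NULL,
                        het_pair_support = NULL, ibd_pairs = NULL,
                        inheritance = NULL, truth = NULL, sim = NULL) {
  new_dataset(variants, evidence, pedigree, samples, genetic_map,
              marker_phase, pair_counts, lane_metrics, het_pair_support,
              ibd_pairs, inheritance, truth, sim)
}

new_dataset <- function(variants, evidence, pedigree, samples,
                        genetic_map = NULL, marker_phase = NULL,
                        pair_counts = NULL, lane_metrics = NULL,
                        het_pair_support = NULL, ibd_pairs = NULL,
                        inheritance = NULL, truth = NULL, sim = NULL) {
  ids <- pedigree$records$id
  bad <- setdiff(unique(evidence$id), ids)
  if (length(bad))
    stop("evidence references individual(s) absent from the pedigree: ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- setdiff(unique(samples$id), ids)
  if (length(bad))
    stop("sample table references individual(s) absent from the pedigree: ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (!is.null(genetic_map) && nrow(genetic_map)) {
    for (ch in unique(genetic_map$chrom)) {
      g <- genetic_map[genetic_map$chrom == ch, ]
      if (is.unsorted(g$pos, strictly = TRUE))
        stop("genetic map positions not strictly increasing on ", ch)
      if (is.unsorted(g$cM))
        stop("genetic map cM not non-decreasing on ", ch)
    }
  }
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
  structure(list(
    variants = variants, evidence = evidence, pedigree = pedigree,
    samples = samples,
    genetic_map = if (is.null(genetic_map))
      empty(chrom = character(0), pos = integer(0), cM = numeric(0))
      else genetic_map,
    marker_phase = if (is.null(marker_phase))
      empty(id = character(0), marker_site = character(0),
            marker_chrom = character(0), marker_pos = integer(0),
            paternal_allele = integer(0)) else marker_phase,
    pair_counts = if (is.null(pair_counts))
      empty(proband = character(0), dnm_site = character(0),
            marker_site = character(0), n_ref_allele1 = integer(0),
            n_ref_allele2 = integer(0), n_alt_allele1 = integer(0),
            n_alt_allele2 = integer(0), n_multi = integer(0))
      else pair_counts,
    lane_metrics = lane_metrics, het_pair_support = het_pair_support,
    ibd_pairs = ibd_pairs,
    inheritance = if (is.null(inheritance))
      empty(offspring = character(0), site_id = character(0),
            proband_hap = character(0), seg_cm = numeric(0),
            seg_markers = integer(0)) else inheritance,
    truth = truth, sim = sim), class = "dnm_dataset")
}

#' @export
print.dnm_dataset <- function(x, ...) {
  cat("<dnm_dataset>\n")
  cat("  variants:  ", nrow(x$variants), "\n")
  cat("  evidence:  ", nrow(x$evidence), " (individual, site) records\n")
  cat("  pedigree:  ", nrow(x$pedigree$records), " individuals, ",
      length(find_three_generation_families(x$pedigree)),
      " three-generation families\n", sep = "")
  if (!is.null(x$truth))
    cat("  truth:     ", nrow(x$truth$dnms), " planted DNMs, ",
        nrow(x$truth$artifacts), " artifact sites\n", sep = "")
  invisible(x)
}

gt_to_vcf <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")
vcf_to_gt <- c("0/0" = "hom_ref", "0/1" = "het", "1/0" = "het",
               "1/1" = "hom_alt", "./." = "missing",
               "0|0" = "hom_ref", "0|1" = "het", "1|0" = "het",
               "1|1" = "hom_alt", ".|." = "missing")

vcf_header <- function(samples, contigs = NULL) {
  c("##fileformat=VCFv4.2",
    "##source=dnmtrio",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", names(contigs),
              as.integer(contigs)),
    "##FILTER=<ID=gatk_fail,Description=\"Failed the GATK recommended filters\">",
    "##INFO=<ID=GAMRESP,Number=1,Type=Float,Description=\"Transmission GAM response\">",
    "##INFO=<ID=PHASE,Number=1,Type=String,Description=\"Parent of origin (paternal/maternal)\">",
    "##INFO=<ID=PMETHOD,Number=1,Type=String,Description=\"Phasing method (three_gen/read_pair/both)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=F1R2,Number=1,Type=Integer,Description=\"Alt-supporting F1R2 read pairs\">",
    "##FORMAT=<ID=F2R1,Number=1,Type=Integer,Description=\"Alt-supporting F2R1 read pairs\">",
    "##FORMAT=<ID=SCF,Number=1,Type=Float,Description=\"Mean soft-clipped fraction of covering reads\">",
    "##FORMAT=<ID=NF,Number=1,Type=Float,Description=\"Mean N fraction of covering reads\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

#' Write the evidence of a dataset as a multi-sample VCF
#'
#' Per-sample FORMAT fields are GT:AD:DP:GQ:F1R2:F2R1:SCF:NF; samples
#' without evidence at a site are written as missing (\code{.}).  The
#' FILTER column records the GATK filter status.
#'
#' @param ds a \code{dnm_dataset}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_vcf_evidence <- function(ds, path) {
  v <- ds$variants
  samples <- ds$pedigree$records$id
  contigs <- NULL
  if (nrow(ds$genetic_map)) {
    contigs <- tapply(ds$genetic_map$pos, ds$genetic_map$chrom, max)
    contigs <- contigs + as.numeric(contigs)  # headroom beyond last marker
  } else if (nrow(v)) {
    contigs <- tapply(v$pos, v$chrom, max) * 2
  }
  body <- character(0)
  if (nrow(v)) {
    cell <- matrix(".", nrow = nrow(v), ncol = length(samples),
                   dimnames = list(v$site_id, samples))
    ev <- ds$evidence
    cell[cbind(match(ev$site_id, v$site_id), match(ev$id, samples))] <-
      sprintf("%s:%d,%d:%d:%d:%d:%d:%g:%g",
              gt_to_vcf[ev$gt], ev$ref_reads, ev$alt_reads, ev$depth,
              ev$gq, ev$f1r2_alt, ev$f2r1_alt, ev$softclip_frac, ev$n_frac)
    body <- paste(v$chrom, v$pos, v$site_id, v$ref, v$alt, ".",
                  ifelse(v$gatk_pass, "PASS", "gatk_fail"), ".",
                  "GT:AD:DP:GQ:F1R2:F2R1:SCF:NF",
                  apply(cell, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(vcf_header(samples, contigs), body), path)
  invisible(path)
}

parse_vcf_cells <- function(gt_matrix, site_ids) {
  keep <- which(!is.na(gt_matrix) & gt_matrix != "." & gt_matrix != "./.")
  if (!length(keep))
    return(data.frame(site_id = character(0), id = character(0),
                      gt = character(0), ref_reads = integer(0),
                      alt_reads = integer(0), depth = integer(0),
                      gq = integer(0), f1r2_alt = integer(0),
                      f2r1_alt = integer(0), softclip_frac = numeric(0),
                      n_frac = numeric(0), stringsAsFactors = FALSE))
  rows <- ((keep - 1L) %% nrow(gt_matrix)) + 1L
  cols <- ((keep - 1L) %/% nrow(gt_matrix)) + 1L
  parts <- strsplit(gt_matrix[keep], ":", fixed = TRUE)
  bad <- which(lengths(parts) != 8L)
  if (length(bad))
    stop("malformed VCF sample field at record ", site_ids[rows[bad[1]]],
         ", sample ", colnames(gt_matrix)[cols[bad[1]]])
  m <- matrix(unlist(parts), ncol = 8L, byrow = TRUE)
  gt <- vcf_to_gt[m[, 1L]]
  if (anyNA(gt))
    stop("unsupported genotype encoding: ",
         m[which(is.na(gt))[1], 1L])
  ad <- strsplit(m[, 2L], ",", fixed = TRUE)
  data.frame(
    site_id = site_ids[rows], id = colnames(gt_matrix)[cols],
    gt = unname(gt),
    ref_reads = as.integer(vapply(ad, `[[`, "", 1L)),
    alt_reads = as.integer(vapply(ad, `[[`, "", 2L)),
    depth = as.integer(m[, 3L]), gq = as.integer(m[, 4L]),
    f1r2_alt = as.integer(m[, 5L]), f2r1_alt = as.integer(m[, 6L]),
    softclip_frac = as.numeric(m[, 7L]), n_frac = as.numeric(m[, 8L]),
    stringsAsFactors = FALSE)
}

#' Read a multi-sample evidence VCF
#'
#' Reads a VCFv4.2 file with the package's FORMAT layout
#' (GT:AD:DP:GQ:F1R2:F2R1:SCF:NF).  Multi-allelic records are decomposed
#' into one ref/alt pair per alternative allele and flagged
#' \code{multiallelic}; sample fields of decomposed records are attached
#' to the first alternative allele only.
#'
#' @param path VCF file path.
#' @return list with \code{variants} and \code{evidence} data.frames.
#' @export
read_vcf_evidence <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(list(
      variants = data.frame(site_id = character(0), chrom = character(0),
                            pos = integer(0), ref = character(0),
                            alt = character(0), gatk_pass = logical(0),
                            is_snp = logical(0), multiallelic = logical(0),
                            stringsAsFactors = FALSE),
      evidence = parse_vcf_cells(matrix(character(0), 0, 0), character(0))))
  }
  gt <- vcf@gt[, -1, drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  site_ids <- fix$ID
  miss_id <- is.na(site_ids) | site_ids == "."
  site_ids[miss_id] <- paste0(fix$CHROM[miss_id], ":", fix$POS[miss_id])
  ev <- parse_vcf_cells(gt, site_ids)
  vars <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    multi <- length(alts) > 1L
    for (j in seq_along(alts)) {
      vars[[length(vars) + 1L]] <- data.frame(
        site_id = if (j == 1L) site_ids[i]
          else paste0(site_ids[i], "_alt", j),
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[j],
        gatk_pass = identical(fix$FILTER[i], "PASS"),
        is_snp = nchar(fix$REF[i]) == 1L && nchar(alts[j]) == 1L,
        multiallelic = multi, stringsAsFactors = FALSE)
    }
  }
  list(variants = do.call(rbind, vars), evidence = ev)
}

write_ped <- function(ped, path) {
  df <- ped$records
  sex_code <- c(male = 1L, female = 2L, unknown = 0L)
  out <- data.frame(fid = "0", iid = df$id,
                    father = ifelse(is.na(df$father), "0", df$father),
                    mother = ifelse(is.na(df$mother), "0", df$mother),
                    sex = sex_code[df$sex], pheno = 0L,
                    twin_group = ifelse(is.na(df$twin_group), "0",
                                        df$twin_group),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a PED pedigree file with a twin-group column
#'
#' Six standard PED columns (family, individual, father, mother, sex,
#' phenotype) extended with a seventh monozygotic-twin-group label
#' (\code{0} = none).
#'
#' @param path PED file path.
#' @return a \code{dnm_pedigree}.
#' @export
read_ped <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) < 6L) stop("PED file must have at least 6 columns")
  sex <- c("1" = "male", "2" = "female", "0" = "unknown")[df[[5L]]]
  if (anyNA(sex)) stop("PED sex codes must be 0, 1 or 2")
  build_pedigree(data.frame(
    id = df[[2L]], sex = unname(sex), father = df[[3L]], mother = df[[4L]],
    twin_group = if (ncol(df) >= 7L) df[[7L]] else NA_character_,
    stringsAsFactors = FALSE))
}

read_tsv_opt <- function(path, proto) {
  if (!file.exists(path)) return(proto)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) return(proto)
  df
}

#' Export a dataset to a directory of standard-format files
#'
#' Writes the multi-sample VCF, PED(+twin) pedigree, genetic map, marker
#' phase, read-pair counts, lane metrics, heterozygous-pair contamination
#' support, sample table, per-offspring inheritance, parent-child IBD
#' summaries and (when present) truth tables, all loadable by
#' \code{\link{load_dataset}} without loss.
#'
#' @param ds a \code{dnm_dataset}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
export_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  write_vcf_evidence(ds, file.path(dir, "variants.vcf"))
  write_ped(ds$pedigree, file.path(dir, "pedigree.ped"))
  w(ds$genetic_map, "genetic_map.tsv")
  w(ds$marker_phase, "marker_phase.tsv")
  w(ds$pair_counts, "pair_counts.tsv")
  w(ds$samples, "samples.tsv")
  w(ds$inheritance, "inheritance.tsv")
  if (!is.null(ds$lane_metrics)) w(ds$lane_metrics, "lane_metrics.tsv")
  if (!is.null(ds$het_pair_support))
    w(ds$het_pair_support, "het_pair_support.tsv")
  if (!is.null(ds$ibd_pairs)) w(ds$ibd_pairs, "ibd_pairs.tsv")
  if (!is.null(ds$truth)) {
    w(ds$truth$dnms, "truth_dnms.tsv")
    w(ds$truth$artifacts, "truth_artifacts.tsv")
    w(ds$truth$swapped_pairs, "truth_swapped_pairs.tsv")
  }
  invisible(dir)
}

#' Load a dataset from a directory of standard-format files
#'
#' Reads the files written by \code{\link{export_dataset}}:
#' \code{variants.vcf} and \code{pedigree.ped} are required, the TSV
#' tables are optional.  Individuals appearing in the VCF but absent from
#' the pedigree are a consistency error.
#'
#' @param dir dataset directory.
#' @return a \code{dnm_dataset}.
#' @export
load_dataset <- function(dir) {
  vcf_path <- file.path(dir, "variants.vcf")
  ped_path <- file.path(dir, "pedigree.ped")
  if (!file.exists(vcf_path)) stop("missing ", vcf_path)
  if (!file.exists(ped_path)) stop("missing ", ped_path)
  ped <- read_ped(ped_path)
  ve <- read_vcf_evidence(vcf_path)
  bad <- setdiff(unique(ve$evidence$id), ped$records$id)
  if (length(bad))
    stop("VCF sample(s) absent from the pedigree: ",
         paste(bad, collapse = ", "))
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
  samples <- read_tsv_opt(file.path(dir, "samples.tsv"),
    empty(id = ped$records$id, mean_coverage = NA_real_,
          mean_softclip = NA_real_, mean_nfrac = NA_real_))
  truth <- NULL
  if (file.exists(file.path(dir, "truth_dnms.tsv"))) {
    truth <- list(
      dnms = read_tsv_opt(file.path(dir, "truth_dnms.tsv"),
        empty(site_id = character(0), chrom = character(0),
              pos = integer(0), proband = character(0),
              origin = character(0), post_twinning = logical(0))),
      artifacts = read_tsv_opt(file.path(dir, "truth_artifacts.tsv"),
        empty(site_id = character(0), chrom = character(0),
              pos = integer(0), proband = character(0), oxog = logical(0))),
      swapped_pairs = read_tsv_opt(file.path(dir, "truth_swapped_pairs.tsv"),
        empty(id1 = character(0), id2 = character(0))))
  }
  new_dataset(
    variants = ve$variants, evidence = ve$evidence, pedigree = ped,
    samples = samples,
    genetic_map = read_tsv_opt(file.path(dir, "genetic_map.tsv"),
      empty(chrom = character(0), pos = integer(0), cM = numeric(0))),
    marker_phase = read_tsv_opt(file.path(dir, "marker_phase.tsv"), NULL),
    pair_counts = read_tsv_opt(file.path(dir, "pair_counts.tsv"), NULL),
    lane_metrics = read_tsv_opt(file.path(dir, "lane_metrics.tsv"), NULL),
    het_pair_support = read_tsv_opt(file.path(dir, "het_pair_support.tsv"),
                                    NULL),
    ibd_pairs = read_tsv_opt(file.path(dir, "ibd_pairs.tsv"), NULL),
    inheritance = read_tsv_opt(file.path(dir, "inheritance.tsv"), NULL),
    truth = truth)
}

#' Write pipeline results to a directory
#'
#' Writes the high-quality DNM calls as a VCF annotated with the GAM
#' response, consensus parent of origin and phasing method (INFO tags
#' GAMRESP, PHASE, PMETHOD), the full scored candidate table, the phasing
#' and variant summary tables, per-twin checks, and a JSON provenance
#' report (stage counts, configuration, seed).  Output is a pure function
#' of the result object: re-running with the same seed and configuration
#' reproduces the files byte for byte.
#'
#' @param result a \code{dnm_result} from \code{\link{run_pipeline}}.
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "dnm_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cands <- result$candidates
  hq <- cands[!is.na(cands$high_quality) & cands$high_quality, , drop = FALSE]
  phases <- result$phases
  lines <- vcf_header(character(0))
  # drop the FORMAT/sample part of the column header for a site-only VCF
  lines[length(lines)] <- paste(c("#CHROM", "POS", "ID", "REF", "ALT",
                                  "QUAL", "FILTER", "INFO"), collapse = "\t")
  if (nrow(hq)) {
    key <- paste(hq$proband, hq$site_id)
    pkey <- paste(phases$proband, phases$site_id)
    j <- match(key, pkey)
    origin <- ifelse(is.na(j), "unphased", phases$origin[j])
    method <- ifelse(is.na(j), "none", phases$method[j])
    info <- sprintf("GAMRESP=%.4f%s%s", hq$response,
                    ifelse(origin %in% c("paternal", "maternal"),
                           paste0(";PHASE=", origin), ""),
                    ifelse(origin %in% c("paternal", "maternal"),
                           paste0(";PMETHOD=", method), ""))
    ord <- order(hq$chrom, hq$pos, hq$proband)
    lines <- c(lines, paste(hq$chrom[ord], hq$pos[ord],
                            paste0(hq$site_id[ord], "_", hq$proband[ord]),
                            hq$ref[ord], hq$alt[ord], ".",
                            ifelse(hq$gatk_pass[ord], "PASS", "gatk_fail"),
                            info[ord], sep = "\t"))
  }
  writeLines(lines, file.path(out_dir, "dnm_calls.vcf"))
  w <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  w(cands, "candidates.tsv")
  w(result$phase_summary, "phase_summary.tsv")
  w(result$variant_summary, "variant_summary.tsv")
  if (!is.null(result$twin)) w(result$twin$per_twin, "twin_checks.tsv")
  report <- list(stages = as.list(result$report),
                 config = unclass(result$config),
                 seed = if (!is.null(result$seed)) result$seed else NA)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
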