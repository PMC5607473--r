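#' Build a pedigree graph from individual records
#'
#' @param records a data.frame with columns \code{id}, \code{sex}
#'   (\code{"male"}, \code{"female"} or \code{"unknown"}), \code{father},
#'   \code{mother} (ids, or \code{NA}/\code{"0"} for untyped) and optionally
#'   \code{twin_group} (label of a monozygotic twin group, \code{NA}/\code{"0"}
#'   for none).
#' @return An object of class \code{dnm_pedigree}: the normalized record
#'   table plus parent/child indices.  Duplicate ids, sex-inconsistent
#'   parent links and cyclic ancestry are structural errors.
#' @examples
#' ped <- build_pedigree(data.frame(
#'   id = c("F", "M", "P"), sex = c("male", "female", "female"),
#'   father = c(NA, NA, "F"), mother = c(NA, NA, "M")))
#' parents_of(ped, "P")
#' @export
build_pedigree <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "sex") %in% names(records)))
  df <- data.frame(
    id     = as.character(records$id),
    sex    = as.character(records$sex),
    father = if ("father" %in% names(records)) as.character(records$father) else NA_character_,
    mother = if ("mother" %in% names(records)) as.character(records$mother) else NA_character_,
    twin_group = if ("twin_group" %in% names(records)) as.character(records$twin_group) else NA_character_,
    stringsAsFactors = FALSE
  )
  df$father[df$father %in% c("0", "")] <- NA_character_
  df$mother[df$mother %in% c("0", "")] <- NA_character_
  df$twin_group[df$twin_group %in% c("0", "")] <- NA_character_
  if (anyDuplicated(df$id))
    stop("duplicate individual id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (!all(df$sex %in% c("male", "female", "unknown")))
    stop("sex must be one of 'male', 'female', 'unknown'")
  idx <- seq_len(nrow(df)); names(idx) <- df$id
  for (side in c("father", "mother")) {
    p <- df[[side]]
    known <- which(!is.na(p) & p %in% df$id)
    want <- if (side == "father") "male" else "female"
    bad <- known[df$sex[idx[p[known]]] != want]
    if (length(bad))
      stop(side, " of ", paste(df$id[bad], collapse = ", "),
           " is not recorded as ", want)
    if (any(!is.na(p) & p == df$id))
      stop("individual recorded as its own ", side)
  }
  ped <- structure(list(records = df, index = idx), class = "dnm_pedigree")
  # cycle detection: ancestors() throws on a back edge
  for (id in df$id) ancestors_of(ped, id)
  ped
}

#' @export
print.dnm_pedigree <- function(x, ...) {
  df <- x$records
  cat("<dnm_pedigree> ", nrow(df), " individuals (",
      sum(df$sex == "male"), " male, ", sum(df$sex == "female"), " female), ",
      sum(!is.na(df$twin_group)), " in MZ twin groups\n", sep = "")
  invisible(x)
}

ped_ids <- function(ped) ped$records$id

has_individual <- function(ped, id) id %in% ped$records$id

#' Parents and ancestors
#'
#' @param ped a \code{dnm_pedigree}.
#' @param id an individual id present in the pedigree.
#' @return \code{parents_of}: character vector of the recorded parents
#'   (length 0-2).  \code{ancestors_of}: all ancestors of \code{id}.
#' @export
parents_of <- function(ped, id) {
  r <- ped$records[ped$index[[id]], ]
  c(r$father, r$mother)[!is.na(c(r$father, r$mother))]
}

#' @rdname parents_of
#' @export
ancestors_of <- function(ped, id) {
  if (!has_individual(ped, id)) stop("unknown individual: ", id)
  seen <- character(0)
  stack <- parents_of(ped, id)
  while (length(stack)) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    if (cur == id) stop("cyclic ancestry involving ", id)
    if (cur %in% seen || !has_individual(ped, cur)) next
    seen <- c(seen, cur)
    stack <- c(stack, parents_of(ped, cur))
  }
  seen
}

children_of <- function(ped, id) {
  df <- ped$records
  df$id[(!is.na(df$father) & df$father == id) |
        (!is.na(df$mother) & df$mother == id)]
}

#' Monozygotic twin of an individual
#'
#' @inheritParams parents_of
#' @return the co-twin's id, or \code{NA} if \code{id} is not in a twin group.
#' @export
twin_of <- function(ped, id) {
  df <- ped$records
  g <- df$twin_group[ped$index[[id]]]
  if (is.na(g)) return(NA_character_)
  others <- df$id[!is.na(df$twin_group) & df$twin_group == g & df$id != id]
  if (length(others)) others[[1L]] else NA_character_
}

#' Discover trios
#'
#' @inheritParams parents_of
#' @return data.frame with columns \code{proband}, \code{father},
#'   \code{mother}: every individual whose two parents are present.
#' @export
find_trios <- function(ped) {
  df <- ped$records
  ok <- !is.na(df$father) & !is.na(df$mother) &
    df$father %in% df$id & df$mother %in% df$id
  out <- data.frame(proband = df$id[ok], father = df$father[ok],
                    mother = df$mother[ok], stringsAsFactors = FALSE)
  out[order(out$proband), , drop = FALSE]
}

#' Discover three-generation families
#'
#' A three-generation family is a proband with both parents present and at
#' least \code{min_offspring} offspring in the pedigree; such families
#' support the transmission assay and three-generation phasing.
#'
#' @inheritParams parents_of
#' @param min_offspring minimum number of proband offspring (default 2).
#' @return list of families, each a list with \code{proband}, \code{father},
#'   \code{mother} and \code{offspring} (character vector).  Output is
#'   sorted by proband id, hence invariant to record order.
#' @export
find_three_generation_families <- function(ped, min_offspring = 2) {
  trios <- find_trios(ped)
  fams <- list()
  for (i in seq_len(nrow(trios))) {
    off <- sort(children_of(ped, trios$proband[i]))
    if (length(off) >= min_offspring)
      fams[[length(fams) + 1L]] <- list(
        proband = trios$proband[i], father = trios$father[i],
        mother = trios$mother[i], offspring = off)
  }
  fams[order(vapply(fams, `[[`, "", "proband"))]
}

#' Descendants of a parent pair
#'
#' All individuals descending from both members of the pair: the couple's
#' children and, transitively, their descendants.  Individuals related
#' through only one member (half-siblings) are not included.  This is the
#' set excused from the outside-carrier counts, since they could
#' legitimately inherit a DNM that arose in a gamete of the pair.
#'
#' @inheritParams parents_of
#' @param father,mother ids of the pair (both must be in the pedigree).
#' @return character vector of descendant ids (possibly empty).
#' @export
descendants_of_pair <- function(ped, father, mother) {
  if (!has_individual(ped, father)) stop("unknown individual: ", father)
  if (!has_individual(ped, mother)) stop("unknown individual: ", mother)
  df <- ped$records
  kids <- df$id[!is.na(df$father) & df$father == father &
                !is.na(df$mother) & df$mother == mother]
  out <- character(0)
  stack <- kids
  while (length(stack)) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    if (cur %in% out) next
    out <- c(out, cur)
    stack <- c(stack, children_of(ped, cur))
  }
  sort(out)
}

#' Confirm recorded parent-child links from haplotype-sharing summaries
#'
#' A recorded parent-child pair is confirmed when the fraction of the
#' autosomal genetic map over which the two share one haplotype reaches
#' \code{threshold}.  True parent-child pairs share essentially the whole
#' map on one haplotype; sample swaps or misrecorded links share far less.
#'
#' @inheritParams parents_of
#' @param ibd data.frame with columns \code{id1}, \code{id2},
#'   \code{shared_fraction} (fraction of autosomal map length on a shared
#'   haplotype, in [0,1]).
#' @param threshold confirmation threshold (default from
#'   \code{run_config()$relationship_threshold}).
#' @return data.frame \code{id1}, \code{id2}, \code{shared_fraction},
#'   \code{confirmed}.  Summaries for pairs not recorded as parent-child in
#'   the pedigree are dropped with a warning.
#' @export
confirm_relationships <- function(ped, ibd, threshold = 0.45) {
  stopifnot(is.data.frame(ibd),
            all(c("id1", "id2", "shared_fraction") %in% names(ibd)))
  if (any(ibd$shared_fraction < 0 | ibd$shared_fraction > 1))
    stop("shared_fraction must be in [0, 1]")
  is_pc <- logical(nrow(ibd))
  for (i in seq_len(nrow(ibd))) {
    a <- ibd$id1[i]; b <- ibd$id2[i]
    is_pc[i] <- has_individual(ped, a) && has_individual(ped, b) &&
      (a %in% parents_of(ped, b) || b %in% parents_of(ped, a))
  }
  if (any(!is_pc))
    warning(sum(!is_pc), " IBD summar",
            if (sum(!is_pc) == 1) "y" else "ies",
            " for pairs not recorded as parent-child; ignored")
  out <- ibd[is_pc, c("id1", "id2", "shared_fraction"), drop = FALSE]
  out$confirmed <- out$shared_fraction >= threshold
  rownames(out) <- NULL
  out
}
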