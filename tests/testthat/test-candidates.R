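test_that("allelic balance is the alt-read fraction", {
  expect_equal(allelic_balance(10, 10), 0.5)
  expect_equal(allelic_balance(0, 12), 1)
  expect_equal(allelic_balance(17, 3), 0.15)
  expect_true(is.na(allelic_balance(0, 0)))
  expect_error(allelic_balance(-1, 2), "non-negative")
})

test_that("carrier classification applies the likely-carrier rules", {
  sev <- rbind(
    ev_row("s1", "good", gt = "het", ref = 15, alt = 15, gq = 99),
    ev_row("s1", "shallow", gt = "het", ref = 4, alt = 4, gq = 99),
    ev_row("s1", "inside", gt = "het", ref = 15, alt = 15, gq = 99),
    ev_row("s1", "ref", gt = "hom_ref", ref = 30, alt = 0, gq = 99))
  cc <- classify_carriers(sev, excluded = "inside")
  expect_identical(cc$n_possible, 2L)
  expect_identical(cc$n_likely, 1L)
  expect_identical(cc$likely, "good")
  # carrier only inside the excluded set
  cc2 <- classify_carriers(sev[sev$id == "inside", ], excluded = "inside")
  expect_identical(c(cc2$n_possible, cc2$n_likely), c(0L, 0L))
  # boundary: depth exactly 12 / gq exactly 20 are not 'likely'
  b <- ev_row("s1", "b", gt = "het", ref = 6, alt = 6, depth = 12, gq = 20)
  cc3 <- classify_carriers(b, excluded = character(0))
  expect_identical(c(cc3$n_possible, cc3$n_likely), c(1L, 0L))
})

test_that("a clean trio DNM is retained and each printed rule rejects", {
  base_ev <- function(p = ev_row("s1", "P")) rbind(
    p,
    ev_row("s1", "F", gt = "hom_ref", ref = 20, alt = 0),
    ev_row("s1", "M", gt = "hom_ref", ref = 25, alt = 0))
  ds <- trio_dataset(site_row("s1"), base_ev())
  expect_identical(nrow(extract_candidates(ds)), 1L)
  # father with 2 alt-supporting reads
  ev <- base_ev(); ev$alt_reads[ev$id == "F"] <- 2L
  expect_identical(nrow(extract_candidates(trio_dataset(site_row("s1"), ev))), 0L)
  # proband allelic balance 0.10 < 0.15
  ev <- base_ev(ev_row("s1", "P", ref = 27, alt = 3))
  expect_identical(nrow(extract_candidates(trio_dataset(site_row("s1"), ev))), 0L)
  # allelic balance exactly 0.15 is retained (inclusive minimum)
  ev <- base_ev(ev_row("s1", "P", ref = 17, alt = 3))
  expect_identical(nrow(extract_candidates(trio_dataset(site_row("s1"), ev))), 1L)
  # parent allelic balance above 0.05 rejects even with a single alt read
  ev <- base_ev()
  ev$ref_reads[ev$id == "F"] <- 14L; ev$alt_reads[ev$id == "F"] <- 1L
  ev$depth[ev$id == "F"] <- 15L
  expect_identical(nrow(extract_candidates(trio_dataset(site_row("s1"), ev))), 0L)
  # hom-alt proband with 2 reference reads
  ev <- base_ev(ev_row("s1", "P", gt = "hom_alt", ref = 2, alt = 28))
  expect_identical(nrow(extract_candidates(trio_dataset(site_row("s1"), ev))), 0L)
  ev <- base_ev(ev_row("s1", "P", gt = "hom_alt", ref = 1, alt = 29))
  expect_identical(nrow(extract_candidates(trio_dataset(site_row("s1"), ev))), 1L)
  # site-level soft clipping above 10%
  ev <- base_ev(ev_row("s1", "P", scf = 0.12))
  expect_identical(nrow(extract_candidates(trio_dataset(site_row("s1"), ev))), 0L)
  # missing parental evidence: skipped, not called
  ev <- base_ev()[-2, ]
  cands <- extract_candidates(trio_dataset(site_row("s1"), ev))
  expect_identical(nrow(cands), 0L)
  expect_identical(attr(cands, "skipped"), 1L)
})

test_that("11 possible outside carriers reject, 10 are allowed", {
  mk <- function(n_out) {
    ped <- build_pedigree(rbind(
      trio_ped()$records,
      data.frame(id = sprintf("U%02d", seq_len(n_out)), sex = "male",
                 father = NA, mother = NA, twin_group = NA)))
    ev <- rbind(
      ev_row("s1", "P"),
      ev_row("s1", "F", gt = "hom_ref", ref = 20, alt = 0),
      ev_row("s1", "M", gt = "hom_ref", ref = 25, alt = 0),
      do.call(rbind, lapply(sprintf("U%02d", seq_len(n_out)), function(u)
        ev_row("s1", u, gt = "het", ref = 4, alt = 4))))
    trio_dataset(site_row("s1"), ev, ped = ped)
  }
  expect_identical(nrow(extract_candidates(mk(10))), 1L)
  expect_identical(nrow(extract_candidates(mk(11))), 0L)
})

test_that("X sites follow hemizygous male rules", {
  ped_m <- trio_ped(proband_sex = "male")
  x <- site_row("s1", chrom = "X")
  # male proband: father depth 6 suffices on X, het call with 2 ref reads
  # is rejected (hemizygous), alt call with <=1 ref read is kept
  ev <- rbind(ev_row("s1", "P", gt = "het", ref = 1, alt = 25),
              ev_row("s1", "F", gt = "hom_ref", ref = 7, alt = 0),
              ev_row("s1", "M", gt = "hom_ref", ref = 20, alt = 0))
  expect_identical(nrow(extract_candidates(trio_dataset(x, ev, ped = ped_m))), 1L)
  ev2 <- ev; ev2$ref_reads[1] <- 2L
  expect_identical(nrow(extract_candidates(trio_dataset(x, ev2, ped = ped_m))), 0L)
  # autosomal father depth 7 would fail
  a <- site_row("s1", chrom = "chr1")
  expect_identical(nrow(extract_candidates(trio_dataset(a, ev, ped = ped_m))), 0L)
  # female proband on X follows autosomal parent-depth rules
  ev3 <- ev; ev3$ref_reads[1] <- 13L; ev3$alt_reads[1] <- 13L
  expect_identical(nrow(extract_candidates(trio_dataset(x, ev3, ped = trio_ped()))), 0L)
  ev3$ref_reads[2] <- 15L; ev3$depth[2] <- 15L
  expect_identical(nrow(extract_candidates(trio_dataset(x, ev3, ped = trio_ped()))), 1L)
})

test_that("proband-level bounds drop all candidates of a proband", {
  cands <- data.frame(proband = c(rep("A", 3), rep("B", 2)),
                      site_id = sprintf("s%d", 1:5),
                      stringsAsFactors = FALSE)
  sm <- data.frame(id = c("A", "B"), mean_softclip = c(0.12, 0.05),
                   mean_nfrac = c(0.001, 0.005))
  out <- filter_probands(cands, sm)
  expect_identical(unique(out$candidates$proband), "B")
  expect_identical(out$excluded_probands$reason, "mean_softclip")
  # candidate-count bound
  many <- data.frame(proband = "C", site_id = sprintf("s%d", 1:301),
                     stringsAsFactors = FALSE)
  sm2 <- data.frame(id = "C", mean_softclip = 0.02, mean_nfrac = 0.001)
  out2 <- filter_probands(many, sm2)
  expect_identical(nrow(out2$candidates), 0L)
  out3 <- filter_probands(many[1:300, ], sm2)
  expect_identical(nrow(out3$candidates), 300L)
})

test_that("extraction matches the rule-by-rule oracle on randomized trios", {
  ds <- random_trio_dataset(n_trios = 1000, seed = 123)
  got <- extract_candidates(ds)
  want <- oracle_extract(ds)
  expect_identical(nrow(got), nrow(want))
  expect_identical(paste(got$proband, got$site_id),
                   paste(want$proband, want$site_id))
  expect_identical(got$n_possible_outside, want$n_possible_outside)
  expect_identical(got$n_likely_outside, want$n_likely_outside)
})

test_that("tightening any threshold never adds candidates", {
  ds <- random_trio_dataset(n_trios = 150, seed = 7)
  base <- extract_candidates(ds)
  key <- function(x) paste(x$proband, x$site_id)
  tighter <- list(run_config(min_proband_ab = 0.3),
                  run_config(min_parent_depth = 20),
                  run_config(max_parent_alt = 0),
                  run_config(max_possible_carriers = 2),
                  run_config(max_site_softclip = 0.05))
  for (cfg in tighter)
    expect_true(all(key(extract_candidates(ds, cfg)) %in% key(base)))
})

test_that("planted germline DNMs with sequenced parents are retained", {
  sim <- cohort_sim()
  ds <- sim$ds
  cands <- extract_candidates(ds)
  tr <- ds$truth$dnms
  ped <- ds$pedigree$records
  fa <- ped$father[match(tr$proband, ped$id)]
  mo <- ped$mother[match(tr$proband, ped$id)]
  evk <- paste(ds$evidence$site_id, ds$evidence$id)
  fdep <- ds$evidence$depth[match(paste(tr$site_id, fa), evk)]
  mdep <- ds$evidence$depth[match(paste(tr$site_id, mo), evk)]
  eligible <- !is.na(fdep) & fdep >= 12 & !is.na(mdep) & mdep >= 12
  got <- paste(tr$site_id, tr$proband) %in%
    paste(cands$site_id, cands$proband)
  expect_gte(mean(got[eligible]), 0.95)
})
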