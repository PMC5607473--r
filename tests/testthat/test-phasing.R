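three_gen_off <- function(hap, gt = "het", ref = 15, alt = 15,
                          depth = ref + alt, seg_cm = 5, seg_markers = 500,
                          id = "O") {
  data.frame(id = id, sex = "female", hap = hap, gt = gt,
             ref_reads = as.integer(ref), alt_reads = as.integer(alt),
             depth = as.integer(depth), seg_cm = seg_cm,
             seg_markers = as.integer(seg_markers), stringsAsFactors = FALSE)
}

test_that("three-generation phasing votes by carrier status and haplotype", {
  # carrier on the paternal haplotype -> paternal
  expect_identical(phase_by_three_gen(three_gen_off("paternal"))$origin,
                   "paternal")
  # non-carrier on the paternal haplotype -> maternal
  expect_identical(phase_by_three_gen(
    three_gen_off("paternal", "hom_ref", ref = 30, alt = 0))$origin,
    "maternal")
  # conflicting votes -> unphased
  off <- rbind(three_gen_off("paternal", id = "O1"),
               three_gen_off("maternal", id = "O2"))
  expect_identical(phase_by_three_gen(off)$origin, "unphased")
  # short shared segment -> abstain -> unphased
  expect_identical(phase_by_three_gen(
    three_gen_off("paternal", seg_cm = 0.5))$origin, "unphased")
  expect_identical(phase_by_three_gen(
    three_gen_off("paternal", seg_markers = 150))$origin, "unphased")
  # segment exactly at the bounds is eligible
  expect_identical(phase_by_three_gen(
    three_gen_off("paternal", seg_cm = 0.8, seg_markers = 200))$origin,
    "paternal")
})

test_that("read-pair tracing requires single-sided alt support", {
  mp <- data.frame(marker_site = c("m1", "m2", "m3"),
                   paternal_allele = c(1L, 2L, 1L))
  pc <- function(a1, a2, r1 = 0, r2 = 0, multi = 0,
                 marker = c("m1", "m2", "m3")[seq_along(a1)]) {
    data.frame(marker_site = marker, n_ref_allele1 = r1, n_ref_allele2 = r2,
               n_alt_allele1 = a1, n_alt_allele2 = a2, n_multi = multi)
  }
  # alt linked to the paternal allele at 3 markers, maternal side zero
  r <- phase_by_read_tracing(pc(a1 = c(3, 0, 2), a2 = c(0, 2, 0)), mp)
  expect_identical(r$origin, "paternal")
  expect_identical(r$support$paternal, 7)
  # support on both sides -> unphased
  expect_identical(phase_by_read_tracing(
    pc(a1 = c(5, 0, 0), a2 = c(2, 0, 0)), mp)$origin, "unphased")
  # only multi-haplotype pairs -> unphased
  expect_identical(phase_by_read_tracing(
    pc(a1 = 0, a2 = 0, multi = 4, marker = "m1"), mp)$origin, "unphased")
  # ref-allele pairings never assign origin
  expect_identical(phase_by_read_tracing(
    pc(a1 = 0, a2 = 0, r1 = 8, marker = "m1"), mp)$origin, "unphased")
  # unresolved markers are dropped
  expect_identical(phase_by_read_tracing(
    pc(a1 = 6, a2 = 0, marker = "m9"), mp)$origin, "unphased")
})

test_that("consensus merges methods and flags discordance", {
  p <- function(o, m) list(origin = o, method = m, support = list())
  expect_identical(consensus_phase(p("paternal", "three_gen"),
                                   p("paternal", "read_pair"))$origin,
                   "paternal")
  expect_identical(consensus_phase(p("paternal", "three_gen"),
                                   p("maternal", "read_pair"))$origin,
                   "discordant")
  expect_identical(consensus_phase(p("unphased", "three_gen"),
                                   p("maternal", "read_pair"))$origin,
                   "maternal")
  expect_identical(consensus_phase(p("unphased", "three_gen"),
                                   p("unphased", "read_pair"))$origin,
                   "unphased")
})

test_that("the phasing summary satisfies the union set identity", {
  set.seed(9)
  for (rep in 1:20) {
    n <- 200
    tg <- sample(c("paternal", "maternal", "unphased"), n, TRUE)
    rp <- sample(c("paternal", "maternal", "unphased"), n, TRUE)
    cons <- mapply(function(a, b) consensus_phase(
      list(origin = a), list(origin = b))$origin, tg, rp)
    ph <- data.frame(three_gen = tg, read_pair = rp, origin = cons)
    s <- summarize_phasing(ph, n)
    g <- function(k) s$count[s$set == k]
    expect_identical(g("consensus"),
                     g("three_gen") + g("read_pair") - g("both") -
                       g("discordant"))
  }
  expect_identical(nrow(summarize_phasing(NULL, 0)), 0L)
})

test_that("consensus never invents an origin absent from both methods", {
  for (a in c("paternal", "maternal", "unphased"))
    for (b in c("paternal", "maternal", "unphased")) {
      o <- consensus_phase(list(origin = a), list(origin = b))$origin
      if (o %in% c("paternal", "maternal")) expect_true(o %in% c(a, b))
    }
})

test_that("error-free read tracing recovers every planted origin", {
  ds <- simulate_dataset(sim_config(n_families = 40, tracing_error = 0,
                                    seq_error = 0, artifact_rate = 0,
                                    somatic_fraction = 0, seed = 31))
  cands <- extract_candidates(ds)
  ph <- phase_dnms(ds, cands)
  tr <- ds$truth$dnms
  j <- match(paste(ph$proband, ph$site_id),
             paste(tr$proband, tr$site_id))
  phased <- ph$origin %in% c("paternal", "maternal") & !is.na(j)
  expect_gt(sum(phased), 100)
  expect_identical(mean(ph$origin[phased] == tr$origin[j[phased]]), 1)
  # read tracing alone is also perfect at zero error
  rp <- ph$read_pair %in% c("paternal", "maternal") & !is.na(j)
  expect_gt(sum(rp), 100)
  expect_identical(mean(ph$read_pair[rp] == tr$origin[j[rp]]), 1)
})

test_that("a forced paternal simulator yields only paternal phases", {
  ds <- simulate_dataset(sim_config(n_families = 10, paternal_fraction = 1,
                                    artifact_rate = 0, somatic_fraction = 0,
                                    seed = 13))
  expect_true(all(ds$truth$dnms$origin == "paternal"))
  cands <- extract_candidates(ds)
  ph <- phase_dnms(ds, cands)
  phased <- ph$origin %in% c("paternal", "maternal")
  expect_gt(sum(phased), 20)
  expect_true(all(ph$origin[phased] == "paternal"))
})
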