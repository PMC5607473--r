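test_that("pedigree construction validates structure", {
  ped <- trio_ped()
  expect_setequal(parents_of(ped, "P"), c("F", "M"))
  expect_error(build_pedigree(data.frame(
    id = c("A", "A"), sex = c("male", "male"),
    father = NA, mother = NA)), "duplicate")
  expect_error(build_pedigree(data.frame(
    id = "A", sex = "male", father = "A", mother = NA)), "own father")
  expect_error(build_pedigree(data.frame(
    id = c("F", "M", "P"), sex = c("female", "female", "male"),
    father = c(NA, NA, "F"), mother = c(NA, NA, "M"))), "not recorded as")
  # cyclic ancestry across two individuals
  expect_error(build_pedigree(data.frame(
    id = c("A", "B"), sex = c("male", "male"),
    father = c("B", "A"), mother = c(NA, NA))), "cyclic")
})

test_that("ancestors follow the three-generation chain", {
  ped <- build_pedigree(data.frame(
    id = c("G1", "G2", "P", "S", "O"),
    sex = c("male", "female", "male", "female", "female"),
    father = c(NA, NA, "G1", NA, "P"),
    mother = c(NA, NA, "G2", NA, "S"),
    stringsAsFactors = FALSE))
  expect_setequal(ancestors_of(ped, "O"), c("P", "S", "G1", "G2"))
})

test_that("three-generation family discovery needs both parents and >=2 offspring", {
  mk <- function(n_off, drop_father = FALSE) {
    ids <- c("F", "M", "P", "S", sprintf("O%d", seq_len(n_off)))
    df <- data.frame(
      id = ids,
      sex = c("male", "female", "male", "female",
              rep("female", n_off)),
      father = c(NA, NA, if (drop_father) NA else "F", NA,
                 rep("P", n_off)),
      mother = c(NA, NA, "M", NA, rep("S", n_off)),
      stringsAsFactors = FALSE)
    build_pedigree(df)
  }
  expect_length(find_three_generation_families(mk(2)), 1L)
  expect_length(find_three_generation_families(mk(1)), 0L)
  expect_length(find_three_generation_families(mk(3, drop_father = TRUE)), 0L)
  # invariant to record order
  ped <- mk(2)
  shuf <- build_pedigree(ped$records[c(5, 3, 1, 6, 2, 4), ])
  f1 <- find_three_generation_families(ped)
  f2 <- find_three_generation_families(shuf)
  expect_identical(f1, f2)
})

test_that("descendants of a pair match the brute-force closure", {
  # fixed pedigree with a grandchild through the proband's sibling
  ped <- build_pedigree(data.frame(
    id = c("F", "M", "P", "B", "S1", "S2", "GP", "GB"),
    sex = c("male", "female", "male", "female", "female", "male",
            "female", "male"),
    father = c(NA, NA, "F", "F", NA, NA, "P", "S2"),
    mother = c(NA, NA, "M", "M", NA, NA, "S1", "B"),
    stringsAsFactors = FALSE))
  got <- descendants_of_pair(ped, "F", "M")
  expect_identical(got, oracle_descendants(ped, "F", "M"))
  expect_true(all(c("P", "B", "GP", "GB") %in% got))
  expect_false(any(c("S1", "S2") %in% got))
  # childless pair
  expect_length(descendants_of_pair(ped, "S2", "S1"), 0L)
  # randomized pedigrees up to 50 individuals
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(10:50, 1)
    ids <- sprintf("I%02d", seq_len(n))
    sex <- sample(c("male", "female"), n, TRUE)
    father <- mother <- rep(NA_character_, n)
    for (i in 3:n) {
      # parents only among earlier individuals: acyclic by construction
      males <- ids[seq_len(i - 1)][sex[seq_len(i - 1)] == "male"]
      females <- ids[seq_len(i - 1)][sex[seq_len(i - 1)] == "female"]
      if (length(males) && length(females) && runif(1) < 0.7) {
        father[i] <- sample(males, 1)
        mother[i] <- sample(females, 1)
      }
    }
    ped <- build_pedigree(data.frame(id = ids, sex = sex, father = father,
                                     mother = mother,
                                     stringsAsFactors = FALSE))
    pairs <- unique(stats::na.omit(data.frame(f = father, m = mother,
                                              stringsAsFactors = FALSE)))
    for (k in seq_len(min(4, nrow(pairs))))
      expect_identical(descendants_of_pair(ped, pairs$f[k], pairs$m[k]),
                       oracle_descendants(ped, pairs$f[k], pairs$m[k]))
  }
})

test_that("haplotype sharing confirms true links and flags swaps", {
  ped <- trio_ped()
  ibd <- data.frame(id1 = c("F", "M"), id2 = c("P", "P"),
                    shared_fraction = c(0.98, 0.02))
  out <- confirm_relationships(ped, ibd, threshold = 0.45)
  expect_identical(out$confirmed, c(TRUE, FALSE))
  # non parent-child pairs are dropped with a warning
  expect_warning(
    out2 <- confirm_relationships(ped, data.frame(
      id1 = "F", id2 = "M", shared_fraction = 0.5)), "ignored")
  expect_identical(nrow(out2), 0L)
})

test_that("planted sample swaps are exactly the unconfirmed pairs", {
  ds <- simulate_dataset(sim_config(n_families = 15, n_sample_swaps = 4,
                                    seed = 5))
  out <- confirm_relationships(ds$pedigree, ds$ibd_pairs)
  bad <- out[!out$confirmed, c("id1", "id2")]
  sw <- ds$truth$swapped_pairs
  expect_identical(nrow(bad), nrow(sw))
  expect_setequal(paste(bad$id1, bad$id2), paste(sw$id1, sw$id2))
})
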