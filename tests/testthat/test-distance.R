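mutate_at_sites <- function(seq, sites) {
  ch <- strsplit(seq, "")[[1]]
  for (s in sites) ch[s] <- setdiff(c("A", "C", "G", "T"), ch[s])[1]
  paste(ch, collapse = "")
}

test_that("p-distance counts mismatches over comparable columns only", {
  expect_equal(p_distance("ACGTACGT", "ACGTACGT"), 0)
  set.seed(41)
  a <- random_seq(1000)
  b <- mutate_at_sites(a, c(10, 500))
  expect_equal(p_distance(a, b), 0.002)
  # ambiguity columns are skipped entirely
  a2 <- "ACGTAAAA"
  b2 <- "NCGTAAAA"
  expect_equal(p_distance(a2, b2), 0)
  expect_error(p_distance("ACGT", "ACGTA"), "equal")
  expect_error(p_distance("NNNN", "ACGT"), "comparable")
})

test_that("p-distance is symmetric, zero on identity and within [0,1]", {
  set.seed(42)
  for (i in 1:20) {
    a <- random_seq(200)
    b <- mutate_at_sites(a, sample(200, sample(0:40, 1)))
    expect_equal(p_distance(a, b), p_distance(b, a))
    expect_gte(p_distance(a, b), 0)
    expect_lte(p_distance(a, b), 1)
    expect_equal(p_distance(a, a), 0)
  }
})

test_that("near-identical clones collapse to one representative", {
  set.seed(43)
  base <- random_seq(1254)
  clones <- tibble::tibble(
    id = sprintf("c%02d", 1:5),
    seq = rep(base, 5)
  )
  reps <- dedup_clones(clones)
  expect_equal(nrow(reps), 1)
  expect_equal(reps$n_members, 5)

  # A,B one site apart (p ~ 0.0008 < 0.001); C ten sites from both
  a <- base
  b <- mutate_at_sites(base, 7)
  c3 <- mutate_at_sites(base, seq(100, 1000, length.out = 10))
  reps2 <- dedup_clones(tibble::tibble(id = c("a", "b", "c"), seq = c(a, b, c3)))
  expect_equal(nrow(reps2), 2)
})

test_that("the dedup threshold is strict and ties go to the smallest id", {
  base <- strrep("ACGG", 500) # 2000 bp
  two_off <- mutate_at_sites(base, c(1, 2)) # exactly p = 0.001
  reps <- dedup_clones(tibble::tibble(id = c("x", "y"), seq = c(base, two_off)),
                       threshold = 0.001)
  expect_equal(nrow(reps), 2) # p == threshold stays separate

  # frequency tie between two distinct-but-close sequences: smallest id wins
  one_off <- mutate_at_sites(base, 1)
  reps2 <- dedup_clones(tibble::tibble(id = c("b1", "a1"),
                                       seq = c(base, one_off)))
  expect_equal(nrow(reps2), 1)
  expect_equal(reps2$id, "a1")
})

test_that("dedup is idempotent on its own representatives", {
  set.seed(44)
  base <- random_seq(800)
  clones <- tibble::tibble(
    id = sprintf("c%02d", 1:12),
    seq = c(rep(base, 4),
            rep(mutate_at_sites(base, 3), 2),
            rep(mutate_at_sites(base, seq(50, 500, by = 50)), 3),
            rep(mutate_at_sites(base, seq(20, 780, by = 20)), 3))
  )
  reps <- dedup_clones(clones)
  again <- dedup_clones(reps[, c("id", "seq")])
  expect_equal(again$seq, reps$seq)
  expect_true(all(again$n_members == 1))
  # representatives are pairwise >= threshold apart
  if (nrow(reps) > 1) {
    for (i in 1:(nrow(reps) - 1)) {
      for (j in (i + 1):nrow(reps)) {
        expect_gte(p_distance(reps$seq[i], reps$seq[j]), 0.001)
      }
    }
  }
})

test_that("chimeras are flagged only when parent clades are divergent enough", {
  set.seed(45)
  refs <- simulate_reference_set(n_clades = 3, n_refs_per_clade = 2,
                                 seq_length = 600, seed = 450)
  L <- nchar(refs$seq[1])
  a_ref <- refs$seq[refs$clade == "A"][1]
  c_ref <- refs$seq[refs$clade == "C"][1]

  pure <- tibble::tibble(id = "pure", seq = a_ref)
  res_pure <- chimera_screen(pure, refs)
  expect_false(res_pure$flagged)
  expect_equal(res_pure$clade_5p, "A")

  splice <- paste0(substr(a_ref, 1, L %/% 2), substr(c_ref, L %/% 2 + 1, L))
  res <- chimera_screen(tibble::tibble(id = "chi", seq = splice), refs)
  expect_true(res$flagged)
  expect_equal(c(res$clade_5p, res$clade_3p), c("A", "C"))

  # parents below min_divergence: discordance is not called chimeric
  res2 <- chimera_screen(tibble::tibble(id = "chi", seq = splice), refs,
                         min_divergence = 0.5)
  expect_false(res2$flagged)

  short <- tibble::tibble(id = "s", seq = substr(refs$seq[1], 1, 150))
  refs_short <- refs |> dplyr::mutate(seq = substr(seq, 1, 150))
  expect_false(chimera_screen(short, refs_short)$screenable)
})
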