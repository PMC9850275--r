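# brute-force O(n^2) contact enumerator, independent of count_contacts
brute_force_total <- function(structures, geom) {
  total <- 0L
  for (s in structures) {
    res <- s$residues
    n <- nrow(res)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        r <- sqrt(sum((unlist(res[j, c("cax", "cay", "caz")]) -
                         unlist(res[i, c("cax", "cay", "caz")]))^2))
        same <- res$chain[i] == res$chain[j]
        sep_ok <- !same || abs(res$resno[j] - res$resno[i]) >= geom$min_seq_sep
        if (r >= geom$r_min && r < geom$r_max && sep_ok) total <- total + 1L
      }
    }
  }
  total
}

test_that("a close 2-residue pair counts once, and the separation filter works", {
  res <- make_helix(4, seed = 1)$residues[c(1, 3), ]
  s2 <- new_structure("P2", res)
  g1 <- bin_geometry(n_theta = 2, n_phi = 2, n_omega = 2, min_seq_sep = 1)
  # residues 1 and 3 of a helix are ~5.2 A apart: inside [3, 16)
  expect_equal(count_contacts(s2, g1)$total, 1)
  g3 <- bin_geometry(n_theta = 2, n_phi = 2, n_omega = 2, min_seq_sep = 3)
  expect_equal(count_contacts(s2, g3)$total, 0)
})

test_that("counts match brute-force enumeration on helix fixture sets", {
  geom <- toy_geom()
  for (nstr in c(1L, 3L, 5L)) {
    hs <- toy_helices(nstr, len = 20L, seed = 40L + nstr)
    cc <- count_contacts(hs, geom)
    expect_equal(cc$total, brute_force_total(hs, geom))
    expect_equal(sum(cc$counts$n), cc$total)
  }
})

test_that("an empty structure list gives a zero tensor", {
  cc <- count_contacts(list(), toy_geom())
  expect_equal(cc$total, 0)
  expect_equal(nrow(cc$counts), 0L)
})

test_that("uniform counts invert to exactly zero energy", {
  geom <- bin_geometry(n_r = 2, n_theta = 2, n_phi = 2, n_omega = 2)
  cc <- count_contacts(list(), geom)
  cc$counts <- expand.grid(pt = seq_len(210L), idx = seq_len(geom$n_bins))
  cc$counts$n <- 7L
  cc$total <- sum(cc$counts$n)
  map <- derive_potential(cc)
  expect_equal(max(abs(map$E)), 0)
})

test_that("a doubled-probability bin at RT = 0.593 scores -0.411 kcal/mol", {
  # single pair type with one bin at twice the reference frequency:
  # approximate the closed form by large counts so the pseudo-count
  # washes out, then compare with -RT log 2
  geom <- bin_geometry(n_r = 4, n_theta = 1, n_phi = 1, n_omega = 1)
  cc <- count_contacts(list(), geom)
  # pair type 1 puts probability 1/2 in bin 1 (= twice the uniform
  # reference 1/4); the other pair types are uniform and dominate the
  # pooled reference
  other <- expand.grid(pt = 2:210, idx = 1:4)
  other$n <- 4e8
  cc$counts <- rbind(data.frame(pt = 1L, idx = 1:4,
                                n = c(2e6, 2e6 / 3, 2e6 / 3, 2e6 / 3)),
                     other)
  cc$total <- sum(cc$counts$n)
  map <- derive_potential(cc, rt = 0.593, pseudo = 1)
  expect_equal(map$E[1, 1], -0.593 * log(2), tolerance = 1e-4)
  expect_equal(-0.593 * log(2), -0.411, tolerance = 1e-3)
})

test_that("derivation matches an independent log-ratio recomputation", {
  geom <- bin_geometry(n_r = 3, n_theta = 2, n_phi = 2, n_omega = 2)
  set.seed(8)
  nb <- geom$n_bins
  dense <- matrix(rpois(nb * 210, 3), nb, 210)
  cc <- structure(list(
    counts = data.frame(pt = rep(seq_len(210), each = nb),
                        idx = rep(seq_len(nb), 210),
                        n = as.vector(dense)),
    geom = geom, total = sum(dense), n_structures = 0L),
    class = "contact_counts")
  map <- derive_potential(cc, rt = 0.593, pseudo = 1)
  # straight reimplementation
  obs <- dense + 1
  pobs <- sweep(obs, 2, colSums(obs), "/")
  pref <- (rowSums(dense) + 1) / sum(rowSums(dense) + 1)
  expect_equal(map$E, -0.593 * log(pobs / pref), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("observed and reference probabilities are normalised", {
  geom <- toy_geom()
  cc <- count_contacts(toy_helices(3), geom)
  map <- derive_potential(cc)
  C <- matrix(0, geom$n_bins, 210)
  C[cbind(cc$counts$idx, cc$counts$pt)] <- cc$counts$n
  pobs <- sweep(C + 1, 2, colSums(C + 1), "/")
  expect_equal(colSums(pobs), rep(1, 210), tolerance = 1e-12)
  pref <- (rowSums(C) + 1) / sum(rowSums(C) + 1)
  expect_equal(sum(pref), 1, tolerance = 1e-12)
  # and E reproduces from them
  expect_equal(map$E, -map$rt * log(pobs / pref), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("counting a structure set twice doubles counts and leaves E unchanged", {
  geom <- toy_geom()
  hs <- toy_helices(2)
  c1 <- count_contacts(hs, geom)
  c2 <- count_contacts(c(hs, hs), geom)
  expect_equal(c2$total, 2 * c1$total)
  m1 <- derive_potential(c1, pseudo = 1e-9)
  m2 <- derive_potential(c2, pseudo = 2e-9)
  # with pseudo-counts scaled along, energies are identical
  expect_equal(m2$E, m1$E, tolerance = 1e-6)
})

test_that("energy lookup is symmetric and zero outside the window", {
  geom <- toy_geom()
  map <- make_synthetic_potential(seed = 5, geom = geom, mode = "random")
  set.seed(10)
  for (i in 1:50) {
    f1 <- random_frame()
    f2 <- random_frame()
    f2$origin <- f1$origin + stats::rnorm(3, sd = 4)
    dij <- pair_descriptor(f1, f2, 5L)
    dji <- pair_descriptor(f2, f1, -5L)
    a <- sample(AA_CODES, 1); b <- sample(AA_CODES, 1)
    expect_identical(energy(map, a, b, dij), energy(map, b, a, dji))
  }
  far <- pair_descriptor(
    build_frame(c(-1, 0, 0), c(0, 0, 0), c(1, 1, 0)),
    transform_frame(build_frame(c(-1, 0, 0), c(0, 0, 0), c(1, 1, 0)),
                    diag(3), c(geom$r_max + 1, 0, 0)), 5L)
  expect_equal(energy(map, "A", "G", far), 0)
})

test_that("derived maps have exchange-symmetric energies for same-type pairs", {
  geom <- toy_geom()
  map <- derive_potential(count_contacts(toy_helices(3), geom))
  set.seed(11)
  for (i in 1:20) {
    f1 <- random_frame()
    f2 <- random_frame()
    f2$origin <- f1$origin + stats::rnorm(3, sd = 4)
    dij <- pair_descriptor(f1, f2, 5L)
    dji <- pair_descriptor(f2, f1, -5L)
    expect_identical(energy(map, "L", "L", dij),
                     energy(map, "L", "L", dji))
  }
})

test_that("blacklist exclusion removes ids and homologs", {
  hs <- toy_helices(3)
  expect_length(rebuild_exclusion(hs, excluded_ids = "FIX2"), 2L)
  expect_length(rebuild_exclusion(hs, excluded_ids = character()), 3L)
  # a homolog: same sequence as FIX1 -> same cluster -> removed
  seq1 <- orientddg:::structure_sequence(hs[[1]])
  surv <- rebuild_exclusion(hs, excluded_sequences = seq1)
  expect_false("FIX1" %in% vapply(surv, function(s) s$id, character(1)))
})
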