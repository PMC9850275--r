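toy_map <- function(seed = 5) {
  make_synthetic_potential(seed = seed, geom = toy_geom(), mode = "random",
                           magnitude = 0.6)
}

test_that("contacts match a brute-force distance scan on a helix", {
  s <- make_helix(25, coord_noise = 0.2, seed = 21)
  geom <- toy_geom()
  for (site in c(1L, 12L, 25L)) {
    cs <- contacts_of(s, "A", site, geom = geom)
    ca <- as.matrix(s$residues[, c("cax", "cay", "caz")])
    d <- sqrt(colSums((t(ca) - ca[site, ])^2))
    expected <- which(d >= geom$r_min & d < geom$r_max &
                        abs(seq_len(25) - site) >= geom$min_seq_sep)
    expect_equal(cs$contacts, expected)
  }
})

test_that("an isolated residue has an empty contact set and ddg 0 with warning", {
  res <- make_helix(3, seed = 2)$residues
  res$resno <- c(1L, 50L, 100L)
  res[2, c("cax", "cay", "caz")] <- c(100, 0, 0)
  res[2, c("nx", "ny", "nz")] <- c(99, 0, 0)
  res[2, c("cx", "cy", "cz")] <- c(101, 1, 0)
  res[3, c("cax", "cay", "caz")] <- c(200, 0, 0)
  res[3, c("nx", "ny", "nz")] <- c(199, 0, 0)
  res[3, c("cx", "cy", "cz")] <- c(201, 1, 0)
  s <- new_structure("ISO", res)
  cs <- contacts_of(s, "A", 50L, geom = toy_geom())
  expect_length(cs$contacts, 0L)
  expect_warning(
    p <- predict_ddg(s, "A", 50L, s$residues$aa[2], "W",
                     weight_set(), toy_map()),
    "empty contact set")
  expect_equal(p$ddg, 0)
})

test_that("identity mutations and constant maps predict exactly zero", {
  s <- make_helix(20, coord_noise = 0.2, seed = 22)
  map <- toy_map()
  wt <- s$residues$aa[10]
  p <- predict_ddg(s, "A", 10L, wt, wt, weight_set(), map,
                   override = TRUE)
  expect_identical(p$ddg, 0)
  # constant map: both sums see the same contact count -> cancellation
  mapc <- map
  mapc$E[] <- 0.7
  p2 <- predict_ddg(s, "A", 10L, wt, setdiff(AA_CODES, wt)[1],
                    weight_set(), mapc)
  expect_equal(p2$ddg, 0, tolerance = 1e-12)
})

test_that("the wild-type identity check fires without override", {
  s <- make_helix(10, sequence = strrep("A", 10), seed = 1)
  expect_error(predict_ddg(s, "A", 5L, "V", "L", weight_set(), toy_map()),
               "mismatch")
  expect_s3_class(predict_ddg(s, "A", 5L, "V", "L", weight_set(),
                              toy_map(), override = TRUE),
                  "ddg_prediction")
})

test_that("forward and reverse predictions on one structure are exact negations", {
  map <- toy_map()
  set.seed(30)
  for (i in 1:100) {
    s <- make_helix(18, coord_noise = 0.3,
                    seed = sample.int(1e6, 1), id = "RND")
    site <- sample(3:16, 1)
    wt <- s$residues$aa[site]
    mut <- sample(setdiff(AA_CODES, wt), 1)
    w <- weight_set(stats::runif(12, 0.2, 3))
    fwd <- predict_ddg(s, "A", site, wt, mut, w, map)
    rev <- predict_ddg(s, "A", site, mut, wt, w, map, override = TRUE)
    expect_equal(fwd$ddg, -rev$ddg, tolerance = 1e-10)
  }
})

test_that("ddg decomposes exactly into its two terms", {
  s <- make_helix(20, coord_noise = 0.2, seed = 23)
  wt <- s$residues$aa[8]
  mut <- setdiff(AA_CODES, wt)[3]
  p <- predict_ddg(s, "A", 8L, wt, mut, toy_true_weights(), toy_map())
  expect_identical(p$ddg, p$term_mut - p$term_wt)
  expect_equal(nrow(p$breakdown), p$n_contacts)
})

test_that("coordinates outside the contact set do not change ddg", {
  s <- make_helix(30, coord_noise = 0.2, seed = 24)
  map <- toy_map()
  cs <- contacts_of(s, "A", 3L, geom = map$geom)
  outside <- setdiff(seq_len(30), c(3L, cs$contacts))
  far <- outside[outside > max(cs$contacts)]
  wt <- s$residues$aa[3]
  mut <- setdiff(AA_CODES, wt)[1]
  w <- toy_true_weights()
  p0 <- predict_ddg(s, "A", 3L, wt, mut, w, map)
  s$residues[far, c("cax", "cay", "caz")] <-
    s$residues[far, c("cax", "cay", "caz")] + 100
  s$residues[far, c("nx", "ny", "nz")] <-
    s$residues[far, c("nx", "ny", "nz")] + 100
  s$residues[far, c("cx", "cy", "cz")] <-
    s$residues[far, c("cx", "cy", "cz")] + 100
  p1 <- predict_ddg(s, "A", 3L, wt, mut, w, map)
  expect_identical(p1$ddg, p0$ddg)
})

test_that("ddg is linear in the map and quadratic in the weights", {
  s <- make_helix(20, coord_noise = 0.2, seed = 25)
  map <- toy_map()
  wt <- s$residues$aa[10]
  mut <- setdiff(AA_CODES, wt)[2]
  w <- toy_true_weights()
  p <- predict_ddg(s, "A", 10L, wt, mut, w, map)
  map3 <- map
  map3$E <- 3 * map$E
  expect_equal(predict_ddg(s, "A", 10L, wt, mut, w, map3)$ddg,
               3 * p$ddg, tolerance = 1e-12)
  w2 <- weight_set(2 * w$w)
  expect_equal(predict_ddg(s, "A", 10L, wt, mut, w2, map)$ddg,
               4 * p$ddg, tolerance = 1e-12)
})

test_that("direct/reverse on identical structures gives delta = 0", {
  s <- make_helix(20, coord_noise = 0.2, seed = 26)
  wt <- s$residues$aa[10]
  mut <- setdiff(AA_CODES, wt)[1]
  pr <- predict_reverse(s, s, "A", 10L, wt, mut, toy_true_weights(),
                        toy_map(), override = TRUE)
  expect_equal(pr$delta, 0, tolerance = 1e-12)
})

test_that("delta grows from zero with backbone perturbation of the mutant", {
  s <- make_helix(20, coord_noise = 0.2, seed = 27)
  map <- toy_map()
  w <- toy_true_weights()
  noise_levels <- c(0, 0.05, 0.2, 0.6)
  cols <- c("nx", "ny", "nz", "cax", "cay", "caz", "cx", "cy", "cz")
  # average |delta| over sites: binning makes any single site stepwise
  deltas <- vapply(noise_levels, function(noise) {
    set.seed(99)
    pert <- matrix(stats::rnorm(20 * 9), 20, 9)
    sm <- s
    sm$residues[, cols] <- sm$residues[, cols] + noise * pert
    mean(vapply(5:15, function(site) {
      wt <- s$residues$aa[site]
      mut <- setdiff(AA_CODES, wt)[1]
      abs(predict_reverse(s, sm, "A", site, wt, mut, w, map,
                          override = TRUE)$delta)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(deltas[1], 0, tolerance = 1e-12)
  # growth trend away from zero with perturbation size
  expect_true(all(deltas[-1] > 0))
  expect_gt(deltas[4], deltas[2])
})

test_that("predict_table reports unresolvable records instead of failing", {
  hs <- toy_helices(2, len = 15)
  map <- toy_map()
  wt5 <- hs[["FIX1"]]$residues$aa[5]
  recs <- mut_recs(
    mut_rec(id = "FIX1", resno = 5L, wt = wt5,
            mut = setdiff(AA_CODES, wt5)[1]),
    mut_rec(id = "MISSING", resno = 1L))
  out <- predict_table(recs, hs, toy_true_weights(), map)
  expect_false(is.na(out$ddg_pred[1]))
  expect_true(is.na(out$ddg_pred[2]))
  expect_match(out$note[2], "missing structure")
})
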