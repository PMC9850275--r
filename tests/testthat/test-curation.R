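test_that("condition window boundaries are inclusive", {
  recs <- mut_recs(
    mut_rec(resno = 1L, temp = 25, pH = 7),     # interior: kept
    mut_rec(resno = 2L, temp = 41, pH = 7),     # hot: dropped
    mut_rec(resno = 3L, temp = 25, pH = 4.5),   # acid: dropped
    mut_rec(resno = 4L, temp = 40, pH = 9),     # on both bounds: kept
    mut_rec(resno = 5L, temp = 10, pH = 5),     # lower bounds: kept
    mut_rec(resno = 6L, temp = NA, pH = 7))     # missing: dropped (default)
  out <- filter_conditions(recs)
  expect_equal(out$resno, c(1L, 4L, 5L))
  st <- attr(out, "stage")
  expect_equal(st$input, 6L)
  expect_equal(st$removed + st$surviving, st$input)
  expect_setequal(st$removed_records$reason[st$removed_records$resno == 3],
                  "pH window")
  # keep mode retains records with missing conditions
  out2 <- filter_conditions(recs, missing = "keep")
  expect_true(6L %in% out2$resno)
})

test_that("replicate groups merge to the standard-conditions record or die", {
  recs <- mut_recs(
    mut_rec(resno = 1L, ddg = -1.0, temp = 30, pH = 7.5),
    mut_rec(resno = 1L, ddg = -1.2, temp = 25, pH = 7.0),
    mut_rec(resno = 2L, ddg = -1.0, temp = 25, pH = 7),
    mut_rec(resno = 2L, ddg = 0.8, temp = 25, pH = 7),
    mut_rec(resno = 3L, ddg = 2.0, temp = 37, pH = 8))
  out <- merge_replicates(recs)
  # group 1: spread 0.2 -> keep (25, 7.0) record
  expect_equal(out$ddg[out$resno == 1L], -1.2)
  # group 2: spread 1.8 > 1.0 -> excluded entirely
  expect_false(2L %in% out$resno)
  # singleton survives untouched
  expect_equal(out$ddg[out$resno == 3L], 2.0)
  st <- attr(out, "stage")
  expect_equal(st$input, 5L)
  expect_equal(st$removed, 3L)
})

test_that("ddg range bounds are inclusive", {
  recs <- mut_recs(
    mut_rec(resno = 1L, ddg = -7.0),
    mut_rec(resno = 2L, ddg = -7.1),
    mut_rec(resno = 3L, ddg = 5.0),
    mut_rec(resno = 4L, ddg = 5.1),
    mut_rec(resno = 5L, ddg = 0))
  out <- filter_ddg_range(recs)
  expect_equal(out$resno, c(1L, 3L, 5L))
})

test_that("structure screen enforces resolution, monomer and backbone", {
  h <- make_helix(10, sequence = strrep("A", 10), seed = 1, id = "GOOD")
  bad_res <- h; bad_res$id <- "BADRES"; bad_res$resolution <- 2.6
  edge_res <- h; edge_res$id <- "EDGE"; edge_res$resolution <- 2.5
  olig <- h; olig$id <- "OLIG"; olig$oligomeric_state <- "oligomer"
  structures <- list(GOOD = h, BADRES = bad_res, EDGE = edge_res,
                     OLIG = olig)
  recs <- mut_recs(
    mut_rec(id = "GOOD", resno = 5L),
    mut_rec(id = "BADRES", resno = 5L),
    mut_rec(id = "EDGE", resno = 5L),
    mut_rec(id = "OLIG", resno = 5L),
    mut_rec(id = "GOOD", resno = 99L),     # unresolvable site
    mut_rec(id = "ABSENT", resno = 1L))
  out <- filter_structures(recs, structures)
  expect_equal(out$id, c("GOOD", "EDGE"))
  st <- attr(out, "stage")
  reasons <- st$removed_records$reason
  expect_setequal(reasons, c("resolution", "not monomeric",
                             "incomplete backbone", "missing structure"))
})

test_that("ligand proximity uses a strict 5 A cutoff on heavy atoms", {
  h <- make_helix(6, sequence = strrep("A", 6), seed = 1, id = "LIG")
  # residue 1 has N at the origin and CA, C further along +x, so a
  # ligand on the -x axis is closest to N, at exactly the offset chosen
  n1 <- unlist(h$residues[1, c("nx", "ny", "nz")])
  near <- h
  near$het <- data.frame(elem = "C", x = n1[1] - 4.9, y = n1[2],
                         z = n1[3], group = "LIG_A_1")
  at5 <- h
  at5$het <- data.frame(elem = "C", x = n1[1] - 5.0, y = n1[2],
                        z = n1[3], group = "LIG_A_1")
  recs <- mut_rec(id = "LIG", resno = 1L)
  out_near <- filter_ligand_proximity(recs, list(LIG = near))
  expect_equal(nrow(out_near), 0L)
  out_at5 <- filter_ligand_proximity(recs, list(LIG = at5))
  expect_equal(nrow(out_at5), 1L)   # exactly 5.0 A: kept (strict <)
  out_none <- filter_ligand_proximity(recs, list(LIG = h))
  expect_equal(nrow(out_none), 1L)  # no HETATM: vacuously kept
})

test_that("balancing caps each ordered pair class with the alanine priority", {
  set.seed(7)
  # 20 A->G records, 18 destabilizing, across several families
  recs <- do.call(rbind, lapply(1:20, function(i) {
    mut_rec(resno = i, wt = "A", mut = "G",
            ddg = if (i <= 18) -1 else 1,
            family = paste0("f", (i %% 4) + 1))
  }))
  out <- balance(recs, cap = 15L, seed = 3L)
  expect_equal(nrow(out), 15L)
  removed <- attr(out, "stage")$removed_records
  # all removals are destabilizing-and-alanine (priority tier 1)
  expect_true(all(removed$ddg < 0))
  # both stabilizing records survive
  expect_equal(sum(out$ddg > 0), 2L)
  # a class at the cap is untouched
  recs15 <- recs[1:15, ]
  expect_equal(nrow(balance(recs15, cap = 15L, seed = 3L)), 15L)
  # determinism
  out2 <- balance(recs, cap = 15L, seed = 3L)
  expect_identical(out$resno, out2$resno)
})

test_that("balancing never erases a family while alternatives exist", {
  recs <- rbind(
    do.call(rbind, lapply(1:9, function(i) {
      mut_rec(resno = i, wt = "A", mut = "G", ddg = -1, family = "big")
    })),
    mut_rec(resno = 10L, wt = "A", mut = "G", ddg = -2, family = "solo"))
  out <- balance(recs, cap = 5L, seed = 1L)
  expect_equal(nrow(out), 5L)
  expect_true("solo" %in% out$family)
})

test_that("balancing only removes records and changes no fields", {
  set.seed(8)
  recs <- do.call(rbind, lapply(1:30, function(i) {
    mut_rec(resno = i, wt = "V", mut = "L",
            ddg = stats::rnorm(1), family = paste0("f", i %% 5))
  }))
  out <- balance(recs, cap = 15L, seed = 2L)
  expect_equal(nrow(out), 15L)
  expect_true(all(paste(out$resno, out$ddg) %in%
                    paste(recs$resno, recs$ddg)))
})

test_that("the full pipeline bookkeeping sums exactly", {
  h <- make_helix(12, sequence = strrep("A", 12), seed = 1, id = "PIPE")
  structures <- list(PIPE = h)
  set.seed(9)
  recs <- do.call(rbind, lapply(1:40, function(i) {
    mut_rec(id = "PIPE", resno = (i %% 10) + 1L, wt = "A",
            mut = sample(c("G", "V", "W"), 1),
            ddg = stats::rnorm(1, -1, 2.5),
            temp = sample(c(25, 60), 1, prob = c(0.8, 0.2)),
            pH = sample(c(7, 3), 1, prob = c(0.8, 0.2)),
            family = paste0("f", i %% 3))
  }))
  out <- curate(recs, structures, cap = 3L, seed = 5L)
  rep <- attr(out, "report")
  total_removed <- sum(vapply(rep$stages, function(s) s$removed, numeric(1)))
  expect_equal(rep$input, total_removed + rep$surviving)
  expect_equal(rep$surviving, nrow(out))
  for (st in rep$stages) {
    expect_equal(st$input, st$removed + st$surviving)
  }
})

test_that("filters are idempotent", {
  set.seed(10)
  recs <- do.call(rbind, lapply(1:25, function(i) {
    mut_rec(resno = i, ddg = stats::rnorm(1, 0, 4),
            temp = sample(c(25, 70), 1), pH = sample(c(7, 2), 1),
            family = paste0("f", i %% 4))
  }))
  once <- filter_conditions(recs)
  twice <- filter_conditions(once)
  expect_identical(twice[names(recs)], once[names(recs)])
  once <- filter_ddg_range(recs)
  expect_identical(filter_ddg_range(once)[names(recs)], once[names(recs)])
  once <- merge_replicates(recs)
  expect_identical(merge_replicates(once)[names(recs)], once[names(recs)])
  once <- balance(recs, cap = 5L, seed = 2L)
  expect_identical(balance(once, cap = 5L, seed = 2L)[names(recs)],
                   once[names(recs)])
})

test_that("the blacklist filter removes exact mutation matches", {
  recs <- mut_recs(mut_rec(resno = 1L), mut_rec(resno = 2L))
  out <- filter_blacklist(recs, mut_rec(resno = 2L))
  expect_equal(out$resno, 1L)
})

test_that("dataset_summary computes the descriptive statistics", {
  recs <- mut_recs(
    mut_rec(resno = 1L, ddg = -2, wt = "A", family = "f1"),
    mut_rec(resno = 2L, ddg = -1, wt = "V", mut = "L", family = "f1"),
    mut_rec(resno = 3L, ddg = 1, wt = "K", mut = "R", family = "f2"),
    mut_rec(resno = 4L, ddg = 2, wt = "D", mut = "A", family = "f3"))
  s <- dataset_summary(recs)
  expect_equal(s$n, 4L)
  expect_equal(s$n_families, 3L)
  expect_equal(s$pct_destabilizing, 50)
  expect_equal(s$pct_stabilizing, 50)
  expect_equal(s$pct_alanine, 50)
  expect_equal(s$mean_ddg, 0)
  expect_equal(s$sd_ddg, stats::sd(c(-2, -1, 1, 2)))
})
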