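# Geometric competence filter, leader clustering and the SSM position
# selection logic.

simple_receptor <- function() {
  data.frame(atom = c("OG", "N", "N"), resno = c(160, 87, 161),
             resid = c("SER", "TYR", "MET"),
             x = c(0, 1.5, -1.5), y = c(0, 2.8, 2.8), z = c(0, 0.5, 0.5))
}

# pose with chosen ester-C -> OG distance d1 and carbonyl-O placed near (or
# far from) the oxyanion nitrogens
pose_at <- function(d1, o_near = TRUE) {
  cc <- c(0, 0, d1)
  oo <- if (o_near) c(0, 2.8, 1.0) else c(0, 9, 9)
  make_pose(rbind(cc, oo, cc + c(1.4, 0, 0.4)))
}

test_that("competence needs all three attack distances strictly under 4 A", {
  ps <- pose_set(simple_receptor(),
                 list(pose_at(3.5), pose_at(4.5), pose_at(3.999)),
                 esters = data.frame(group = "E1", ester_c = "C1", carbonyl_o = "O1"),
                 scores = c(-9, -8, -7))
  res <- filter_competent_poses(ps)
  expect_equal(res$competent, c(TRUE, FALSE, TRUE))
  expect_equal(res$d_ester_c_og, c(3.5, 4.5, 3.999), tolerance = 1e-9)
  # carbonyl oxygen out of the oxyanion hole also fails
  ps2 <- pose_set(simple_receptor(), list(pose_at(3.0, o_near = FALSE)),
                  esters = data.frame(group = "E1", ester_c = "C1",
                                      carbonyl_o = "O1"),
                  scores = 0)
  expect_false(filter_competent_poses(ps2)$competent)
  # exactly at the threshold is not competent (strict comparison)
  ps3 <- pose_set(simple_receptor(), list(pose_at(4.0)),
                  esters = data.frame(group = "E1", ester_c = "C1",
                                      carbonyl_o = "O1"),
                  scores = 0)
  expect_false(filter_competent_poses(ps3)$competent)
})

test_that("missing catalytic atoms are reported by residue and atom", {
  rec <- simple_receptor()[-1, ] # drop the serine OG
  ps <- pose_set(rec, list(pose_at(3.5)),
                 esters = data.frame(group = "E1", ester_c = "C1",
                                     carbonyl_o = "O1"),
                 scores = 0)
  expect_error(filter_competent_poses(ps), "OG.*160")
})

test_that("competence matches a brute-force all-pairs distance oracle", {
  fx <- simulate_hotspot_fixtures(hotspot_sites(), noise_free(13),
                                  n_poses = 20, frac_competent = 0.35)
  ps <- fx$poses
  res <- filter_competent_poses(ps)
  rec <- ps$receptor
  at <- function(resno, atom) unlist(rec[rec$resno == resno & rec$atom == atom,
                                         c("x", "y", "z")])
  oracle <- vapply(ps$poses, function(p) {
    ok <- FALSE
    for (g in seq_len(nrow(ps$esters))) {
      cc <- unlist(p[p$atom == ps$esters$ester_c[g], c("x", "y", "z")])
      oo <- unlist(p[p$atom == ps$esters$carbonyl_o[g], c("x", "y", "z")])
      d <- c(sqrt(sum((cc - at(160, "OG"))^2)),
             sqrt(sum((oo - at(87, "N"))^2)),
             sqrt(sum((oo - at(161, "N"))^2)))
      if (all(d < 4)) ok <- TRUE
    }
    ok
  }, logical(1))
  expect_equal(res$competent, oracle)
})

test_that("competence is invariant under a joint rigid-body transform", {
  fx <- simulate_hotspot_fixtures(hotspot_sites(), noise_free(14), n_poses = 10)
  ps <- fx$poses
  before <- filter_competent_poses(ps)$competent
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  shift <- c(5, -3, 2)
  rot <- function(df) {
    m <- t(R %*% t(as.matrix(df[, c("x", "y", "z")]))) +
      matrix(shift, nrow(df), 3, byrow = TRUE)
    df[, c("x", "y", "z")] <- m
    df
  }
  ps2 <- ps
  ps2$receptor <- rot(ps2$receptor)
  ps2$poses <- lapply(ps2$poses, rot)
  expect_equal(filter_competent_poses(ps2)$competent, before)
})

test_that("duplicate poses collapse to one cluster, distant poses split", {
  p <- pose_at(3.5)
  esters <- data.frame(group = "E1", ester_c = "C1", carbonyl_o = "O1")
  dup <- pose_set(simple_receptor(), list(p, p, p), esters, scores = c(-3, -2, -1))
  expect_equal(unique(cluster_poses(dup)$cluster), 1)
  far <- p; far[, c("x", "y", "z")] <- far[, c("x", "y", "z")] + 5 / sqrt(3)
  two <- pose_set(simple_receptor(), list(p, far), esters, scores = c(-3, -2))
  expect_equal(sort(unique(cluster_poses(two)$cluster)), c(1, 2))
})

test_that("leader clustering matches a hand-run of the algorithm", {
  esters <- data.frame(group = "E1", ester_c = "C1", carbonyl_o = "O1")
  base <- pose_at(3.5)
  move <- function(d) { p <- base; p$x <- p$x + d; p }
  # pairwise RMSD between poses i and j is |xi - xj| (pure x translations)
  offsets <- c(0, 0.4, 0.9, 2.0, 2.3, 4.0, 0.2, 2.1, 4.5, 6.0)
  scores <- c(-10, -9, -8, -7, -6, -5, -4, -3, -2, -1)
  ps <- pose_set(simple_receptor(), lapply(offsets, move), esters, scores)
  cl <- cluster_poses(ps, rmsd_threshold = 1)
  # score order is pose order here; leaders arise at offsets 0, 2.0, 4.0, 6.0
  oracle <- rep(NA_integer_, 10)
  leaders <- integer(0)
  for (i in seq_along(offsets)) {
    assigned <- FALSE
    for (l in leaders) if (abs(offsets[i] - offsets[l]) <= 1) {
      oracle[i] <- oracle[l]; assigned <- TRUE; break
    }
    if (!assigned) { leaders <- c(leaders, i); oracle[i] <- length(leaders) }
  }
  expect_equal(cl$cluster, oracle)
  expect_equal(cl$pose[cl$is_leader], leaders)
})

test_that("clustering partitions the set with members near their leaders", {
  fx <- simulate_hotspot_fixtures(hotspot_sites(), noise_free(15),
                                  n_poses = 18, n_clusters = 4)
  ps <- fx$poses
  cl <- cluster_poses(ps, rmsd_threshold = 1)
  expect_setequal(cl$pose, 1:18)
  heavy <- ps$poses[[1]]$atom
  for (k in unique(cl$cluster)) {
    lead <- cl$pose[cl$is_leader & cl$cluster == k]
    a <- as.matrix(ps$poses[[lead]][, c("x", "y", "z")])
    for (m in cl$pose[cl$cluster == k]) {
      b <- as.matrix(ps$poses[[m]][, c("x", "y", "z")])
      expect_lte(sqrt(mean(rowSums((a - b)^2))), 1)
    }
  }
  # mismatched ligand atom sets are refused at construction
  odd <- ps$poses
  odd[[2]] <- odd[[2]][-1, ]
  expect_error(pose_set(ps$receptor, odd, ps$esters, ps$scores), "atom set")
})

test_that("selection reproduces the published candidate set {87, 238, 280}", {
  fx <- simulate_hotspot_fixtures(hotspot_sites(), noise_free(16))
  rep <- select_ssm_positions(fx$energy, fx$conservation,
                              exclusions = ile208_exclusion())
  expect_equal(rep$residue[rep$selected], c(87, 238, 280))
  expect_true(all(rep$hotspot)) # all 13 sit at or below -1 kcal/mol
  # the conserved tryptophan is flagged and deselected
  w185 <- rep[rep$residue == 185, ]
  expect_true(w185$conserved && !w185$selected)
  expect_equal(fx$conservation$rate[fx$conservation$residue == 185], 0.7)
  # the excluded isoleucine carries its reason
  i208 <- rep[rep$residue == 208, ]
  expect_true(i208$excluded && !i208$selected)
  expect_match(i208$reason, "prior engineering")
})

test_that("threshold edges follow the stated inclusivity rules", {
  energy <- data.frame(residue = c(1, 2, 3), mean_dg = c(-1.0, -0.999, -1.5))
  cons <- data.frame(residue = c(1, 2, 3), rate = c(1.2, 2, 1.1999))
  rep <- select_ssm_positions(energy, cons)
  expect_true(rep$hotspot[rep$residue == 1])    # <= -1 inclusive
  expect_false(rep$hotspot[rep$residue == 2])
  expect_false(rep$conserved[rep$residue == 1]) # < 1.2 exclusive
  expect_true(rep$conserved[rep$residue == 3])
  expect_equal(rep$residue[rep$selected], 1)
})

test_that("selection is order-independent and monotone in the energy threshold", {
  fx <- simulate_hotspot_fixtures(hotspot_sites(), noise_free(17))
  shuffle <- sample(nrow(fx$energy))
  r1 <- select_ssm_positions(fx$energy, fx$conservation, ile208_exclusion())
  r2 <- select_ssm_positions(fx$energy[shuffle, ], fx$conservation, ile208_exclusion())
  expect_equal(r1, r2, ignore_attr = TRUE)
  sel_loose <- r1$residue[r1$selected]
  for (thr in c(-1.5, -2.0, -2.5)) {
    sel <- select_ssm_positions(fx$energy, fx$conservation, ile208_exclusion(),
                                dg_threshold = thr)
    expect_true(all(sel$residue[sel$selected] %in% sel_loose))
    sel_loose <- sel$residue[sel$selected]
  }
})

test_that("table mismatches and reasonless exclusions are rejected", {
  energy <- data.frame(residue = c(87, 238), mean_dg = c(-2, -2))
  cons <- data.frame(residue = 87, rate = 1.5)
  expect_error(select_ssm_positions(energy, cons), "238")
  cons2 <- data.frame(residue = c(87, 238), rate = c(1.5, 1.5))
  expect_error(select_ssm_positions(energy, cons2,
                                    exclusions = data.frame(residue = 87, reason = "")),
               "reason")
})

test_that("pose sets survive a PDB + sidecar round trip", {
  dir <- withr::local_tempdir()
  fx <- simulate_hotspot_fixtures(hotspot_sites(), noise_free(19), n_poses = 8)
  paths <- file.path(dir, c("receptor.pdb", "poses.pdb", "esters.csv"))
  write_pose_pdb(fx$poses, paths[1], paths[2], paths[3])
  ps2 <- read_pose_set(paths[1], paths[2], paths[3])
  expect_equal(length(ps2$poses), 8)
  expect_equal(ps2$scores, fx$poses$scores, tolerance = 1e-5)
  expect_equal(filter_competent_poses(ps2)$competent,
               filter_competent_poses(fx$poses)$competent)
  expect_equal(cluster_poses(ps2)$cluster, cluster_poses(fx$poses)$cluster)
})
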