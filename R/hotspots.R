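# Structure-based selection of site-saturation mutagenesis positions:
# geometric filtering of docked polymer-ligand poses for catalytic
# competence, leader clustering of poses, and hotspot calling from
# per-residue binding-energy and conservation tables.

#' Docked pose set container
#'
#' Receptor coordinates plus a set of docked ligand poses sharing one atom
#' set, with the ester groups of the polymer-chain surrogate ligand flagged
#' and a docking score per pose.
#'
#' @param receptor Data frame with columns `atom` (PDB atom name, e.g.
#'   `"OG"`, `"N"`), `resno` (residue number), `x`, `y`, `z` (Angstrom) and
#'   optionally `resid` (3-letter residue name).
#' @param poses List of data frames, one per pose, each with columns
#'   `atom`, `x`, `y`, `z`; all poses must share the same atom names in the
#'   same order.
#' @param esters Data frame flagging ester groups by ligand atom name:
#'   columns `group`, `ester_c`, `carbonyl_o`. Every pose must contain at
#'   least one flagged group.
#' @param scores Numeric docking scores, one per pose (lower = better).
#' @return Object of class `pose_set`.
#' @export
pose_set <- function(receptor, poses, esters, scores) {
  need <- c("atom", "resno", "x", "y", "z")
  if (!all(need %in% names(receptor)))
    stop_input("receptor needs columns: %s", paste(need, collapse = ", "))
  if (!length(poses)) stop_input("need at least one pose")
  ref_atoms <- poses[[1]]$atom
  same <- vapply(poses, function(p) identical(p$atom, ref_atoms), logical(1))
  if (!all(same))
    stop_input("all poses must share the same ligand atom set (mismatch at pose %d)",
               which(!same)[1])
  if (!all(c("group", "ester_c", "carbonyl_o") %in% names(esters)) ||
      nrow(esters) < 1)
    stop_input("esters must flag >= 1 group with columns group, ester_c, carbonyl_o")
  missing <- setdiff(c(esters$ester_c, esters$carbonyl_o), ref_atoms)
  if (length(missing))
    stop_input("ester atom(s) not present in poses: %s",
               paste(missing, collapse = ", "))
  if (length(scores) != length(poses))
    stop_input("need one docking score per pose")
  structure(list(receptor = receptor, poses = poses, esters = esters,
                 scores = as.numeric(scores)),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("Pose set: %d poses (%d ligand atoms, %d flagged ester group(s)), receptor %d atoms\n",
              length(x$poses), nrow(x$poses[[1]]), nrow(x$esters),
              nrow(x$receptor)))
  invisible(x)
}

receptor_atom <- function(receptor, resno, atom) {
  i <- which(receptor$resno == resno & receptor$atom == atom)
  if (length(i) != 1L)
    stop_input("catalytic atom '%s' of residue %d not found in receptor (or ambiguous)",
               atom, resno)
  as.numeric(receptor[i, c("x", "y", "z")])
}

dist3 <- function(a, b) sqrt(sum((a - b)^2))

#' Geometric catalytic-competence filter for docked poses
#'
#' A pose is catalytically competent when, for at least one flagged ester
#' group, all three attack distances are strictly below the threshold: the
#' ester carbon to the gamma-O (atom `OG`) of the catalytic serine, and the
#' carbonyl oxygen to the backbone amide N of each of the two oxyanion-hole
#' residues.
#'
#' @param poses A [pose_set()].
#' @param distance_threshold Angstrom; strict `<` comparison (default 4).
#' @param catalytic_ser Residue number of the nucleophile serine
#'   (default 160, mature-protein numbering).
#' @param oxyanion_residues Residue numbers whose backbone N forms the
#'   oxyanion hole (default `c(87, 161)`).
#' @return Data frame of class `competence_result`: `pose`, `competent`,
#'   `best_group` (ester group minimizing the largest of the three
#'   distances), `d_ester_c_og`, `d_o_n1`, `d_o_n2` for that group.
#' @export
filter_competent_poses <- function(poses, distance_threshold = 4.0,
                                   catalytic_ser = 160,
                                   oxyanion_residues = c(87, 161)) {
  stopifnot(inherits(poses, "pose_set"))
  og <- receptor_atom(poses$receptor, catalytic_ser, "OG")
  n1 <- receptor_atom(poses$receptor, oxyanion_residues[1], "N")
  n2 <- receptor_atom(poses$receptor, oxyanion_residues[2], "N")
  res <- lapply(seq_along(poses$poses), function(ip) {
    p <- poses$poses[[ip]]
    xyz <- function(name) as.numeric(p[match(name, p$atom), c("x", "y", "z")])
    per_group <- lapply(seq_len(nrow(poses$esters)), function(g) {
      cc <- xyz(poses$esters$ester_c[g])
      oo <- xyz(poses$esters$carbonyl_o[g])
      c(d1 = dist3(cc, og), d2 = dist3(oo, n1), d3 = dist3(oo, n2))
    })
    worst <- vapply(per_group, max, numeric(1))
    best <- which.min(worst)
    d <- per_group[[best]]
    data.frame(pose = ip,
               competent = all(d < distance_threshold),
               best_group = poses$esters$group[best],
               d_ester_c_og = d[["d1"]], d_o_n1 = d[["d2"]], d_o_n2 = d[["d3"]])
  })
  out <- do.call(rbind, res)
  structure(out, class = c("competence_result", "data.frame"),
            distance_threshold = distance_threshold)
}

pose_coords <- function(pose, atoms) {
  as.matrix(pose[match(atoms, pose$atom), c("x", "y", "z")])
}

# RMSD without superposition: poses live in the shared receptor frame.
pose_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Greedy leader clustering of docked poses
#'
#' Poses are visited in docking-score order (best first). Each unassigned
#' pose within the RMSD threshold of an existing cluster leader joins that
#' cluster (first leader checked in score order); otherwise it seeds a new
#' cluster. RMSD is computed over ligand heavy atoms without superposition,
#' since all poses share the receptor coordinate frame.
#'
#' @param poses A [pose_set()].
#' @param rmsd_threshold Angstrom (default 1.0).
#' @return Data frame of class `pose_clusters`: `pose`, `score`, `cluster`
#'   (1 = best-scored leader), `is_leader`.
#' @export
cluster_poses <- function(poses, rmsd_threshold = 1.0) {
  stopifnot(inherits(poses, "pose_set"))
  heavy <- poses$poses[[1]]$atom[!grepl("^H", poses$poses[[1]]$atom)]
  if (!length(heavy)) stop_input("poses contain no heavy atoms")
  coords <- lapply(poses$poses, pose_coords, atoms = heavy)
  ord <- order(poses$scores)
  cluster <- integer(length(ord))
  leaders <- integer(0)
  for (ip in ord) {
    assigned <- FALSE
    for (l in leaders) {
      if (pose_rmsd(coords[[ip]], coords[[l]]) <= rmsd_threshold) {
        cluster[ip] <- cluster[l]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      leaders <- c(leaders, ip)
      cluster[ip] <- length(leaders)
    }
  }
  out <- data.frame(pose = seq_along(cluster), score = poses$scores,
                    cluster = cluster,
                    is_leader = seq_along(cluster) %in% leaders)
  structure(out, class = c("pose_clusters", "data.frame"),
            rmsd_threshold = rmsd_threshold)
}

#' Select site-saturation mutagenesis positions
#'
#' Combines hotspot calling from a per-residue binding-energy decomposition
#' (hotspot when mean Delta-G contribution <= `dg_threshold`, inclusive),
#' an evolutionary-conservation filter (conserved when the per-site
#' relative rate < `rate_threshold`, exclusive), and an explicit
#' knowledge-based exclusion list with reasons. A position is selected when
#' it is a hotspot, not conserved and not excluded.
#'
#' @param energy Data frame with columns `residue` (number), `mean_dg`
#'   (kcal/mol) and optionally `sd`.
#' @param conservation Data frame with columns `residue` (or `position`)
#'   and `rate` (relative evolutionary rate, >= 0).
#' @param exclusions Optional data frame with columns `residue`, `reason`;
#'   every excluded residue must carry a non-empty reason.
#' @param dg_threshold Hotspot threshold, kcal/mol (default -1, inclusive).
#' @param rate_threshold Conservation threshold (default 1.2, exclusive;
#'   typically the sequence-average rate).
#' @return Data frame of class `ssm_report`: `residue`, `mean_dg`, `rate`,
#'   `hotspot`, `conserved`, `excluded`, `reason`, `selected`, sorted by
#'   residue number.
#' @export
select_ssm_positions <- function(energy, conservation, exclusions = NULL,
                                 dg_threshold = -1.0, rate_threshold = 1.2) {
  if (!all(c("residue", "mean_dg") %in% names(energy)))
    stop_input("energy table needs columns residue, mean_dg")
  if ("position" %in% names(conservation) && !"residue" %in% names(conservation))
    names(conservation)[names(conservation) == "position"] <- "residue"
  if (!all(c("residue", "rate") %in% names(conservation)))
    stop_input("conservation table needs columns residue (or position), rate")
  if (anyDuplicated(energy$residue))
    stop_input("duplicate residue id(s) in energy table")
  if (any(conservation$rate < 0)) stop_input("conservation rates must be >= 0")
  miss <- setdiff(energy$residue, conservation$residue)
  if (length(miss))
    stop_input("position(s) missing from conservation table: %s",
               paste(sort(miss), collapse = ", "))
  excl <- data.frame(residue = integer(), reason = character())
  if (!is.null(exclusions) && nrow(exclusions)) {
    if (!all(c("residue", "reason") %in% names(exclusions)) ||
        any(!nzchar(exclusions$reason)))
      stop_input("exclusions need columns residue and a non-empty reason")
    excl <- exclusions
  }
  ord <- order(energy$residue)
  res <- energy$residue[ord]
  dg <- energy$mean_dg[ord]
  rate <- conservation$rate[match(res, conservation$residue)]
  hotspot <- dg <= dg_threshold
  conserved <- rate < rate_threshold
  excluded <- res %in% excl$residue
  reason <- ifelse(excluded, excl$reason[match(res, excl$residue)], "")
  out <- data.frame(residue = res, mean_dg = dg, rate = rate,
                    hotspot = hotspot, conserved = conserved,
                    excluded = excluded, reason = reason,
                    selected = hotspot & !conserved & !excluded,
                    row.names = NULL)
  structure(out, class = c("ssm_report", "data.frame"),
            dg_threshold = dg_threshold, rate_threshold = rate_threshold)
}

#' Read per-residue binding-energy table CSV (residue, mean_dg[, sd])
#' @param path CSV path.
#' @return Data frame for [select_ssm_positions()].
#' @export
read_energy_csv <- function(path) read_meta_csv(path)

#' Read per-site conservation-rate table CSV (residue/position, rate)
#' @param path CSV path.
#' @return Data frame for [select_ssm_positions()].
#' @export
read_conservation_csv <- function(path) read_meta_csv(path)

#' Read a pose set from PDB files
#'
#' Reads a receptor PDB and a multi-MODEL ligand-pose PDB (one MODEL per
#' docking pose) with an ester-group sidecar CSV naming the flagged ester
#' carbon and carbonyl oxygen atoms, plus per-pose docking scores.
#'
#' @param receptor_pdb Path to the receptor PDB.
#' @param poses_pdb Path to the multi-model pose PDB.
#' @param ester_map Data frame or CSV path with columns `group`, `ester_c`,
#'   `carbonyl_o` (ligand atom names).
#' @param scores Numeric vector of docking scores (one per model); if NULL,
#'   taken from a `# scores:` metadata line in the ester map CSV.
#' @return A [pose_set()].
#' @export
read_pose_set <- function(receptor_pdb, poses_pdb, ester_map, scores = NULL) {
  rec <- bio3d::read.pdb(receptor_pdb)
  receptor <- data.frame(atom = rec$atom$elety, resno = rec$atom$resno,
                         resid = rec$atom$resid,
                         x = rec$atom$x, y = rec$atom$y, z = rec$atom$z)
  lig <- bio3d::read.pdb(poses_pdb, multi = TRUE)
  atoms <- lig$atom$elety
  xyz <- lig$xyz # one row per MODEL
  poses <- lapply(seq_len(nrow(xyz)), function(m) {
    m3 <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    data.frame(atom = atoms, x = m3[, 1], y = m3[, 2], z = m3[, 3])
  })
  if (is.character(ester_map)) {
    em <- read_meta_csv(ester_map)
    if (is.null(scores)) scores <- attr(em, "metadata")$scores
    ester_map <- em
  }
  if (is.null(scores)) scores <- rep(0, length(poses))
  pose_set(receptor, poses, ester_map, scores)
}
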