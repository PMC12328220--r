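## synthetic_data: toy folds with idealized backbone geometry, orthogroups
## evolved with planted class-dependent substitution rates, and property
## tables with stated couplings to divergence. The generator's defaults are
## the study conditions used throughout the validation suite.

#' Synthetic-orthogroup specification
#'
#' Defaults plant the conservation hierarchy binding site > core > surface
#' (per-site, per-member substitution probabilities 0.02 / 0.2 / 0.5),
#' 0.5 Angstrom coordinate noise, terminal indels, 5-30 members per group,
#' and property couplings that tie abundance positively -- and flux
#' variability and kcat variability negatively -- to the true conservation
#' of the group.
#'
#' @param n_orthogroups number of orthogroups in a corpus.
#' @param n_members inclusive range members are drawn from.
#' @param p_bind,p_core,p_surf per-site substitution probabilities by class.
#' @param sigma_coord Gaussian C-alpha noise, Angstrom.
#' @param indel_prob probability of a terminal deletion per terminus.
#' @param indel_range inclusive length range of terminal deletions.
#' @param abundance,flux_cv,kcat_log_sd linear couplings (intercept alpha,
#'   slope beta on true CR, noise sd sigma).
#' @param phenotype_multiplier substitution-rate multiplier applied to
#'   yes-phenotype species in subgroup simulations.
#' @param og_rate_range range of per-orthogroup multipliers on the core and
#'   surface substitution rates, giving corpora the spread of conservation
#'   seen across real orthogroups (binding-site rates are not scaled).
#' @param blueprint fold blueprint (see \code{default_blueprint}).
#' @return list of class "synthetic_spec".
#' @export
synthetic_spec <- function(n_orthogroups = 10, n_members = c(5, 30),
                           p_bind = 0.02, p_core = 0.2, p_surf = 0.5,
                           sigma_coord = 0.5,
                           indel_prob = 0.5, indel_range = c(1, 6),
                           abundance = list(alpha = 4, beta = 6, sigma = 1),
                           flux_cv = list(alpha = 1.2, beta = -1.0, sigma = 0.15),
                           kcat_log_sd = list(alpha = 1.1, beta = -0.9, sigma = 0.15),
                           phenotype_multiplier = 0.5,
                           og_rate_range = c(0.5, 2.0),
                           blueprint = default_blueprint()) {
  stopifnot(p_bind >= 0, p_bind <= 1, p_core >= 0, p_core <= 1,
            p_surf >= 0, p_surf <= 1, sigma_coord >= 0,
            n_members[1] >= 2)
  structure(list(n_orthogroups = n_orthogroups, n_members = n_members,
                 p_bind = p_bind, p_core = p_core, p_surf = p_surf,
                 sigma_coord = sigma_coord, indel_prob = indel_prob,
                 indel_range = indel_range, abundance = abundance,
                 flux_cv = flux_cv, kcat_log_sd = kcat_log_sd,
                 phenotype_multiplier = phenotype_multiplier,
                 og_rate_range = og_rate_range,
                 blueprint = blueprint),
            class = "synthetic_spec")
}

#' Default fold blueprint: a three-helix bundle with a central pocket
#'
#' 72 residues (three helices of 20 joined by 6-residue coils); the pocket
#' is the three inward-facing mid-helix triplets, mutually adjacent across
#' the bundle triangle.
#'
#' @return list with segments (data.frame type/length) and pocket (indices).
#' @export
default_blueprint <- function() {
  segments <- data.frame(
    type = c("helix", "coil", "helix", "coil", "helix"),
    length = c(20, 6, 20, 6, 20), stringsAsFactors = FALSE)
  list(segments = segments, pocket = c(9:11, 35:37, 61:63))
}

## derive a child seed from a master seed without 32-bit overflow
derive_seed <- function(master, salt, offset = 0) {
  as.integer((as.numeric(master) * salt + offset) %% 2147483629)
}

## sample() treats a length-1 vector as 1:x; guard against that
resample_one <- function(x) if (length(x) == 1) x else sample(x, 1)

## ---- ideal backbone construction (NeRF) ------------------------------------

## place point D given A-B-C, bond |C-D|, angle B-C-D (deg), dihedral
## A-B-C-D (deg)
.nerf <- function(A, B, C, bond, angle, dihedral) {
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

## full-backbone segment from ideal phi/psi; returns list of N/CA/C/O
## matrices (n x 3)
.build_segment_backbone <- function(n, phi, psi, omega = 180) {
  if (length(phi) == 1) phi <- rep(phi, n)
  if (length(psi) == 1) psi <- rep(psi, n)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- .nerf(c(0, 1, 0), N[1, ], CA[1, ], 1.525, 111.2, 0)
  for (i in 2:n) {
    N[i, ] <- .nerf(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.329, 116.2, psi[i - 1])
    CA[i, ] <- .nerf(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458, 121.7, omega)
    C[i, ] <- .nerf(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi[i])
  }
  for (i in seq_len(n)) {
    psi_i <- psi[i]
    O[i, ] <- .nerf(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi_i - 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

.segment_phi_psi <- function(type) {
  switch(type,
         helix = c(-57, -47),
         strand = c(-139, 135),
         stop("unknown segment type: ", type))
}

## rigid transform helpers
.rotation_align <- function(from, to) {
  from <- from / sqrt(sum(from^2)); to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  s <- sqrt(sum(v^2)); cth <- sum(from * to)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    axis <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- axis - sum(axis * from) * from
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  Vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + Vx + Vx %*% Vx * ((1 - cth) / s^2)
}

.rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
}

## R is a column-vector rotation (R %*% v); rows transform as v' = v R^T
.transform_bb <- function(bb, R, t) {
  lapply(bb, function(M) sweep(tcrossprod(M, R), 2, t, `+`))
}

## Kabsch-Sander H-bond count between two backbones (used to register
## antiparallel strand pairs deterministically)
.count_interseg_hbonds <- function(bb1, bb2) {
  N <- rbind(bb1$N, bb2$N); CA <- rbind(bb1$CA, bb2$CA)
  C <- rbind(bb1$C, bb2$C); O <- rbind(bb1$O, bb2$O)
  E <- .hbond_matrix(N, CA, C, O)
  n1 <- nrow(bb1$N)
  blk <- E < -0.5
  sum(blk[seq_len(n1), -seq_len(n1), drop = FALSE]) +
    sum(blk[-seq_len(n1), seq_len(n1), drop = FALSE])
}

## biased self-avoiding walk bridging two anchors with ~3.8 A virtual bonds;
## an optional waypoint steers the first half of the walk (used to route
## linkers over the bundle instead of through it)
.bridge_coil <- function(from, to, n, avoid, max_retries = 100, via = NULL) {
  bond <- 3.8
  for (try in seq_len(max_retries)) {
    pts <- matrix(NA_real_, n, 3)
    cur <- from
    ok <- TRUE
    for (i in seq_len(n)) {
      m <- n - i + 1                       # bonds remaining after this step
      v <- to - cur
      dv <- sqrt(sum(v^2))
      w <- max(0, 1 - (bond * m - dv) / (bond * m))   # pull harder when taut
      tgt <- if (!is.null(via) && i <= n %/% 2 && w < 0.8) via else to
      tv <- tgt - cur
      tdv <- sqrt(sum(tv^2))
      step <- NULL
      for (attempt in 1:20) {
        r <- stats::rnorm(3); r <- r / sqrt(sum(r^2))
        dir <- max(w, 0.5) * tv / max(tdv, 1e-9) + (1 - w + 0.2) * r
        dir <- dir / sqrt(sum(dir^2))
        cand <- cur + bond * dir
        rem <- sqrt(sum((to - cand)^2))
        feasible <- if (m > 1) rem <= bond * m + 0.5 else abs(rem - bond) <= 1.5
        ## self-avoidance excludes the directly bonded predecessor (3.8 A)
        placed_pts <- if (i > 2) pts[seq_len(i - 2), , drop = FALSE] else
          matrix(numeric(0), 0, 3)
        obst <- rbind(avoid, placed_pts)
        clash <- nrow(obst) > 0 &&
          min(rowSums(sweep(obst, 2, cand)^2)) < 16
        if (feasible && !clash) { step <- cand; break }
      }
      if (is.null(step)) { ok <- FALSE; break }
      pts[i, ] <- step
      cur <- step
    }
    if (ok) {
      ## relax toward exact bond lengths between anchors
      chain <- rbind(from, pts, to)
      for (iter in 1:30) {
        for (b in seq_len(nrow(chain) - 1)) {
          d <- chain[b + 1, ] - chain[b, ]
          len <- sqrt(sum(d^2))
          corr <- (len - bond) / 2 * d / max(len, 1e-9)
          if (b > 1) chain[b, ] <- chain[b, ] + corr
          if (b + 1 < nrow(chain)) chain[b + 1, ] <- chain[b + 1, ] - corr
        }
      }
      return(chain[2:(n + 1), , drop = FALSE])
    }
  }
  stop("self-avoidance failure while bridging a coil segment")
}

## approximate backbone for coil residues from the C-alpha trace; only needs
## to be chemically plausible, not H-bond faithful
.approx_backbone_from_ca <- function(ca) {
  n <- nrow(ca)
  N <- C <- O <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    prev <- if (i > 1) ca[i - 1, ] else ca[i, ] - c(3.8, 0, 0)
    nxt <- if (i < n) ca[i + 1, ] else ca[i, ] + c(3.8, 0, 0)
    t <- nxt - prev; t <- t / max(sqrt(sum(t^2)), 1e-9)
    up <- c(0, 0, 1)
    side <- c(t[2] * up[3] - t[3] * up[2],
              t[3] * up[1] - t[1] * up[3],
              t[1] * up[2] - t[2] * up[1])
    if (sqrt(sum(side^2)) < 1e-6) side <- c(1, 0, 0)
    side <- side / sqrt(sum(side^2))
    N[i, ] <- ca[i, ] - 1.2 * t + 0.6 * side
    C[i, ] <- ca[i, ] + 1.2 * t + 0.6 * side
    O[i, ] <- C[i, ] + 1.23 * side
  }
  list(N = N, CA = ca, C = C, O = O)
}

#' Build a toy fold from a blueprint
#'
#' Structured segments (helix, strand) are built with full idealized
#' backbones from canonical phi/psi dihedrals, rigidly placed -- helices on
#' a bundle circle with alternating direction, consecutive strands paired
#' antiparallel at sheet spacing with the axial registry chosen to maximise
#' inter-strand hydrogen bonds -- and joined by self-avoiding coil walks
#' with 3.8 Angstrom virtual bonds. Helices carrying pocket residues are
#' rotated about their own axis so the pocket faces the bundle core, and a
#' packing step shrinks the bundle until all pocket C-alphas are mutually
#' within \code{pocket_within} (guarding against inter-segment clashes).
#' The sequence is drawn uniformly over the 20 canonical amino acids.
#'
#' @param blueprint list(segments, pocket) as from \code{default_blueprint}.
#' @param seed integer seed; identical seeds give identical structures.
#' @param structure_id identifier for the model.
#' @param pocket_within packing target for pocket mutual distance (default
#'   8 Angstrom).
#' @return structure_model with full backbone atoms and pLDDT-like scores.
#' @export
build_toy_fold <- function(blueprint, seed = 1, structure_id = "toy",
                           pocket_within = 8.0) {
  set.seed(seed)
  seg <- blueprint$segments
  stopifnot(all(seg$length >= 3), all(seg$type %in% c("helix", "strand", "coil")))
  n_total <- sum(seg$length)
  pocket <- blueprint$pocket
  stopifnot(all(pocket >= 1 & pocket <= n_total))
  seg_end <- cumsum(seg$length)
  seg_start <- seg_end - seg$length + 1
  struct_idx <- which(seg$type != "coil")
  K <- length(struct_idx)

  ## build structured segments at origin, principal axis on +z
  built <- vector("list", nrow(seg))
  for (k in struct_idx) {
    pp <- .segment_phi_psi(seg$type[k])
    bb <- .build_segment_backbone(seg$length[k], pp[1], pp[2])
    ax <- stats::prcomp(bb$CA)$rotation[, 1]
    if (sum(ax * (bb$CA[nrow(bb$CA), ] - bb$CA[1, ])) < 0) ax <- -ax
    R <- .rotation_align(ax, c(0, 0, 1))
    ctr <- colMeans(bb$CA)
    built[[k]] <- .transform_bb(bb, R, -as.numeric(R %*% ctr))
  }

  place_all <- function(spacing) {
    placed <- built
    all_strand <- all(seg$type[struct_idx] == "strand")
    for (ki in seq_along(struct_idx)) {
      k <- struct_idx[ki]
      dir_up <- ki %% 2 == 1
      if (all_strand) {
        slot <- c(0, spacing * (ki - 1), 0)
      } else if (K == 1) {
        slot <- c(0, 0, 0)
      } else {
        r <- spacing / (2 * sin(pi / K))
        ang <- 2 * pi * (ki - 1) / K
        slot <- c(r * cos(ang), r * sin(ang), 0)
      }
      bb <- placed[[k]]
      if (!dir_up) {
        flip <- .rotation_align(c(0, 0, 1), c(0, 0, -1))
        bb <- .transform_bb(bb, flip, c(0, 0, 0))
      }
      ## rotate about own axis so pocket residues face the bundle centre
      pk_local <- pocket[pocket >= seg_start[k] & pocket <= seg_end[k]] - seg_start[k] + 1
      if (length(pk_local) > 0 && !all_strand && K > 1) {
        best <- NULL; best_val <- Inf
        for (th in seq(0, 2 * pi, length.out = 37)[-37]) {
          cand <- .transform_bb(bb, .rot_z(th), slot)
          val <- sum(cand$CA[pk_local, 1:2, drop = FALSE]^2)
          if (val < best_val) { best_val <- val; best <- cand }
        }
        placed[[k]] <- best
      } else {
        placed[[k]] <- .transform_bb(bb, diag(3), slot)
      }
    }
    ## register consecutive strand pairs by maximising inter-strand H-bonds
    if (all_strand && K >= 2) {
      for (ki in 2:K) {
        k <- struct_idx[ki]; kp <- struct_idx[ki - 1]
        best <- placed[[k]]; best_n <- -1
        for (dz in seq(-3.5, 3.5, by = 0.35)) {
          cand <- .transform_bb(placed[[k]], diag(3), c(0, 0, dz))
          nh <- .count_interseg_hbonds(placed[[kp]], cand)
          if (nh > best_n) { best_n <- nh; best <- cand }
        }
        placed[[k]] <- best
      }
    }
    placed
  }

  all_strand <- all(seg$type[struct_idx] == "strand")
  spacing <- if (all_strand) 4.9 else 10.0
  placed <- place_all(spacing)

  ## packing: shrink bundle until pocket residues are mutually close
  if (length(pocket) > 1 && !all_strand && K > 1) {
    for (iter in 1:12) {
      ca_struct <- matrix(NA_real_, n_total, 3)
      for (k in struct_idx) ca_struct[seg_start[k]:seg_end[k], ] <- placed[[k]]$CA
      pd <- stats::dist(ca_struct[pocket, , drop = FALSE])
      if (max(pd) <= pocket_within) break
      ## clash guard between structured segments
      mind <- Inf
      for (a in seq_along(struct_idx)) {
        for (b in seq_along(struct_idx)) {
          if (b <= a) next
          da <- placed[[struct_idx[a]]]$CA; db <- placed[[struct_idx[b]]]$CA
          d2 <- outer(rowSums(da^2), rowSums(db^2), `+`) - 2 * da %*% t(db)
          mind <- min(mind, sqrt(max(min(d2), 0)))
        }
      }
      if (mind < 4.2) break
      spacing <- spacing * 0.92
      placed <- place_all(spacing)
    }
  }

  ## assemble C-alpha trace; bridge coils between placed segments
  ca <- matrix(NA_real_, n_total, 3)
  for (k in struct_idx) ca[seg_start[k]:seg_end[k], ] <- placed[[k]]$CA
  for (k in which(seg$type == "coil")) {
    idx <- seg_start[k]:seg_end[k]
    ## leave room near the anchors: a 3.8 A step from a helix end is always
    ## close to the end's own helical neighbours (1.5 A rise per residue)
    anchors <- intersect(c(seg_start[k] - (1:5), seg_end[k] + (1:5)),
                         seq_len(n_total))
    avoid_rows <- setdiff(which(stats::complete.cases(ca)), anchors)
    avoid <- ca[avoid_rows, , drop = FALSE]
    if (k > 1 && k < nrow(seg)) {
      from <- ca[seg_start[k] - 1, ]; to <- ca[seg_end[k] + 1, ]
      ## waypoint above/below the bundle on the anchors' side
      mid <- (from + to) / 2
      zs <- sign(mid[3] + 1e-9)
      via <- c(mid[1] * 1.4, mid[2] * 1.4, zs * (abs(mid[3]) + 5))
      ca[idx, ] <- .bridge_coil(from, to, seg$length[k], avoid, via = via)
    } else if (k == 1) {
      to <- ca[seg_end[k] + 1, ]
      from <- to + c(0, 0, 3.8 * (seg$length[k] + 1))
      pts <- .bridge_coil(from, to, seg$length[k], avoid)
      ca[idx, ] <- pts
    } else {
      from <- ca[seg_start[k] - 1, ]
      cur <- from
      for (i in seq_along(idx)) {
        r <- stats::rnorm(3); r <- r / sqrt(sum(r^2))
        r[3] <- r[3] + 1.2 * sign(from[3] + 1e-9)
        r <- r / sqrt(sum(r^2))
        cur <- cur + 3.8 * r
        ca[idx[i], ] <- cur
      }
    }
  }

  ## backbone assembly: ideal for structured segments, approximate for coils
  N <- C <- O <- matrix(NA_real_, n_total, 3)
  for (k in struct_idx) {
    ii <- seg_start[k]:seg_end[k]
    N[ii, ] <- placed[[k]]$N; C[ii, ] <- placed[[k]]$C; O[ii, ] <- placed[[k]]$O
  }
  coil_res <- which(is.na(N[, 1]))
  if (length(coil_res) > 0) {
    approx <- .approx_backbone_from_ca(ca)
    N[coil_res, ] <- approx$N[coil_res, ]
    C[coil_res, ] <- approx$C[coil_res, ]
    O[coil_res, ] <- approx$O[coil_res, ]
  }

  aa <- sample(AA_CANONICAL, n_total, replace = TRUE)
  k10 <- floor(0.1 * n_total)
  plddt_base <- rep(92, n_total)
  if (k10 >= 1) {
    plddt_base[seq_len(k10)] <- 80
    plddt_base[(n_total - k10 + 1):n_total] <- 86
  }
  plddt <- pmin(100, pmax(0, plddt_base + stats::rnorm(n_total, 0, 2)))
  residues <- data.frame(chain = "A", seq_index = seq_len(n_total), aa = aa,
                         resno_author = seq_len(n_total), insert_author = "",
                         x = ca[, 1], y = ca[, 2], z = ca[, 3],
                         plddt = round(plddt, 2), stringsAsFactors = FALSE)
  atoms <- data.frame(
    seq_index = rep(seq_len(n_total), each = 4),
    elety = rep(c("N", "CA", "C", "O"), n_total),
    element = rep(c("N", "C", "C", "O"), n_total),
    x = as.numeric(t(cbind(N[, 1], ca[, 1], C[, 1], O[, 1]))),
    y = as.numeric(t(cbind(N[, 2], ca[, 2], C[, 2], O[, 2]))),
    z = as.numeric(t(cbind(N[, 3], ca[, 3], C[, 3], O[, 3]))),
    stringsAsFactors = FALSE)
  m <- new_structure_model(structure_id, source = "predicted",
                           residues = residues, atoms = atoms)
  attr(m, "pocket") <- pocket
  m
}

#' Plant a ligand next to the pocket of a toy fold
#'
#' Adds a single-residue ligand (a few heavy atoms around the pocket
#' C-alpha centroid) so proximity-based binding-site detection has ground
#' truth to recover.
#'
#' @param s structure_model from \code{build_toy_fold}.
#' @param pocket residue indices (default: the fold's pocket attribute).
#' @param resid ligand residue name (default "LIG").
#' @return structure_model with ligand_atoms set.
#' @export
plant_ligand <- function(s, pocket = attr(s, "pocket"), resid = "LIG") {
  stopifnot(length(pocket) >= 1)
  ctr <- colMeans(ca_coords(s)[pocket, , drop = FALSE])
  offs <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(-0.7, 1.2, 0), c(-0.7, -1.2, 0))
  lig <- data.frame(resid = resid, resno = 9001L,
                    elety = c("C1", "C2", "O1", "N1"),
                    element = c("C", "C", "O", "N"),
                    x = ctr[1] + offs[, 1], y = ctr[2] + offs[, 2],
                    z = ctr[3] + offs[, 3], stringsAsFactors = FALSE)
  s$ligand_atoms <- lig
  s
}

#' Residue classes of an ancestor fold (ground truth)
#'
#' Pocket indices are "bind"; the rest splits into "core"/"surface" by the
#' ancestor's relative solvent accessibility.
#'
#' @param ancestor structure_model.
#' @param pocket pocket indices.
#' @param surface_threshold rSASA cutoff (default 0.25).
#' @param n_points SASA lattice size (default 960).
#' @return character vector bind/core/surface per residue.
#' @export
residue_classes <- function(ancestor, pocket = attr(ancestor, "pocket"),
                            surface_threshold = 0.25, n_points = 960) {
  sasa <- shrake_rupley_sasa(ancestor, n_points = n_points)
  rs <- relative_sasa(sasa, ancestor$residues$aa,
                      surface_threshold = surface_threshold)
  cls <- ifelse(rs$exposure == "surface", "surface", "core")
  cls[pocket] <- "bind"
  cls
}

#' Evolve an orthogroup from an ancestor with planted substitution rates
#'
#' Each member substitutes every site independently with its class
#' probability (replacements uniform over the 19 other amino acids, so the
#' expected per-class identity is 1 - p), receives Gaussian C-alpha noise
#' (applied rigidly per residue so local backbone geometry survives), and
#' may lose a stretch at either terminus. The ancestor joins the group as
#' the reference member.
#'
#' @param ancestor structure_model (typically from \code{build_toy_fold}).
#' @param spec synthetic_spec.
#' @param og_id orthogroup identifier.
#' @param seed RNG seed.
#' @param n_members member count; default drawn from \code{spec$n_members}.
#' @param classes per-residue classes; default from \code{residue_classes}.
#' @param rate_multipliers optional named per-species multiplier on the
#'   substitution probabilities (phenotype subgroup simulations).
#' @param rate_scale orthogroup-level multiplier on the core/surface rates
#'   (drawn from \code{spec$og_rate_range} by \code{generate_corpus}).
#' @return list with og (orthogroup), truth (classes, per-member events,
#'   per-class true rates, cr_true) -- ground truth consistent with the
#'   emitted structures.
#' @export
evolve_orthogroup <- function(ancestor, spec, og_id = "og1", seed = 1,
                              n_members = NULL, classes = NULL,
                              rate_multipliers = NULL, rate_scale = 1) {
  set.seed(seed)
  if (is.null(classes)) classes <- residue_classes(ancestor)
  if (is.null(n_members)) {
    rng <- seq(spec$n_members[1], spec$n_members[2])
    n_members <- if (length(rng) == 1) rng else sample(rng, 1)
  }
  p_class <- c(bind = spec$p_bind,
               core = min(1, spec$p_core * rate_scale),
               surf = min(1, spec$p_surf * rate_scale))
  p_site <- unname(p_class[c(bind = "bind", core = "core",
                             surface = "surf")[classes]])
  L <- nrow(ancestor$residues)
  anc_aa <- strsplit(ancestor$sequence, "")[[1]]
  ref_id <- paste0("sp00_", og_id)
  ref <- ancestor
  ref$structure_id <- ref_id
  structures <- stats::setNames(list(ref), ref_id)
  events <- list()
  ident_frac <- numeric(0)
  for (m in seq_len(n_members)) {
    sp <- sprintf("sp%02d", m)
    mult <- if (!is.null(rate_multipliers) && sp %in% names(rate_multipliers)) {
      rate_multipliers[[sp]]
    } else 1
    p <- pmin(1, p_site * mult)
    hit <- stats::runif(L) < p
    aa <- anc_aa
    for (i in which(hit)) {
      aa[i] <- sample(setdiff(AA_CANONICAL, anc_aa[i]), 1)
    }
    ## rigid per-residue coordinate noise
    shift <- matrix(stats::rnorm(3 * L, 0, spec$sigma_coord), L, 3)
    res <- ancestor$residues
    res$aa <- aa
    res[, c("x", "y", "z")] <- res[, c("x", "y", "z")] + shift
    atoms <- ancestor$atoms
    atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
      shift[atoms$seq_index, , drop = FALSE]
    ## terminal deletions
    keep <- rep(TRUE, L)
    if (stats::runif(1) < spec$indel_prob) {
      k <- resample_one(seq(spec$indel_range[1], spec$indel_range[2]))
      keep[seq_len(min(k, L - 10))] <- FALSE
    }
    if (stats::runif(1) < spec$indel_prob) {
      k <- resample_one(seq(spec$indel_range[1], spec$indel_range[2]))
      keep[(L - min(k, L - 10) + 1):L] <- FALSE
    }
    res <- res[keep, , drop = FALSE]
    res$seq_index <- seq_len(nrow(res))
    atoms <- atoms[keep[atoms$seq_index], , drop = FALSE]
    atoms$seq_index <- match(atoms$seq_index,
                             which(keep))
    mem_id <- paste0(sp, "_", og_id)
    structures[[mem_id]] <- new_structure_model(
      mem_id, source = "predicted", residues = res, atoms = atoms)
    events[[mem_id]] <- list(substituted = which(hit), kept = which(keep))
    ident_frac <- c(ident_frac, mean(!hit))
  }
  og <- new_orthogroup(og_id, reference_ids = ref_id, structures = structures)
  truth <- list(classes = classes, pocket = attr(ancestor, "pocket"),
                events = events,
                p_class = p_class,
                cr_true = mean(ident_frac),
                cr_true_by_class = vapply(
                  c(bind = "bind", core = "core", surface = "surface"),
                  function(k) {
                    idx <- which(classes == k)
                    if (length(idx) == 0) return(NA_real_)
                    mean(vapply(events, function(e) {
                      mean(!(idx %in% e$substituted))
                    }, numeric(1)))
                  }, numeric(1)))
  list(og = og, truth = truth)
}

#' Generate a corpus of synthetic orthogroups
#'
#' Builds one toy fold per orthogroup (seeded independently, so folds
#' differ in sequence and coil paths) and evolves members under the spec's
#' planted rates. EC classes and pathway labels are assigned cyclically by
#' blueprint family for enrichment exercises.
#'
#' @param spec synthetic_spec.
#' @param seed master seed; orthogroup seeds derive from it.
#' @return list of per-orthogroup lists (og, truth, ancestor), plus
#'   attributes "ec_class" and "pathways".
#' @export
generate_corpus <- function(spec, seed = 1) {
  out <- vector("list", spec$n_orthogroups)
  set.seed(seed)
  scales <- stats::runif(spec$n_orthogroups, spec$og_rate_range[1],
                         spec$og_rate_range[2])
  for (g in seq_len(spec$n_orthogroups)) {
    og_id <- sprintf("og%03d", g)
    anc <- build_toy_fold(spec$blueprint, seed = derive_seed(seed, 1000, g),
                          structure_id = paste0("anc_", og_id))
    ev <- evolve_orthogroup(anc, spec, og_id = og_id, seed = derive_seed(seed, 2000, g),
                            rate_scale = scales[g])
    out[[g]] <- list(og = ev$og, truth = ev$truth, ancestor = anc)
  }
  names(out) <- vapply(out, function(x) x$og$og_id, character(1))
  attr(out, "ec_class") <- stats::setNames(
    rep_len(1:7, spec$n_orthogroups), names(out))
  attr(out, "pathways") <- stats::setNames(
    sprintf("pw%d", rep_len(1:5, spec$n_orthogroups)), names(out))
  out
}

#' Property tables coupled to true conservation
#'
#' Draws per-orthogroup properties from the spec's linear couplings on true
#' CR plus Gaussian noise: abundance rises with conservation, while flux
#' variability and kcat variability fall. Auxiliary columns (flux median,
#' species count, inhibitor count, ppi degree, EC class, pathway) complete
#' the standard property-table shape.
#'
#' @param corpus output of \code{generate_corpus}.
#' @param spec synthetic_spec.
#' @param seed RNG seed.
#' @return data.frame keyed by og_id.
#' @export
generate_property_tables <- function(corpus, spec, seed = 1) {
  set.seed(seed)
  cr <- vapply(corpus, function(x) x$truth$cr_true, numeric(1))
  n <- length(cr)
  draw <- function(cp) cp$alpha + cp$beta * cr + stats::rnorm(n, 0, cp$sigma)
  data.frame(
    og_id = names(corpus),
    cr_true = unname(cr),
    abundance_log2 = unname(draw(spec$abundance)),
    flux_median = unname(exp(stats::rnorm(n, 0, 1))),
    flux_cv = unname(pmax(0.01, draw(spec$flux_cv))),
    flux_n_species = unname(stats::rbinom(n, 26, stats::plogis(2 * (cr - 0.5)))),
    kcat_log_sd = unname(pmax(0.01, draw(spec$kcat_log_sd))),
    n_inhibitors = unname(stats::rpois(n, exp(0.5 + 2 * cr))),
    ppi_degree = unname(stats::rpois(n, exp(1 + 1.5 * cr))),
    enzyme_class = unname(attr(corpus, "ec_class")[names(corpus)]),
    pathway = unname(attr(corpus, "pathways")[names(corpus)]),
    stringsAsFactors = FALSE)
}
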