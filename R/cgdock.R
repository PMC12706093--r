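# Coarse-grained Brownian-dynamics docking simulator: R-side system
# construction and drivers. Internal units: nm, ns, pN (energies pN nm).

#' Configuration of the coarse-grained docking simulation
#'
#' Physical constants follow the study conditions: 0.1 ns timestep,
#' cytosolic viscosity 2.21 cP, membrane bending rigidity 0.8e-19 J,
#' SV outer diameter 42.5 nm above a 180 nm periodic membrane patch,
#' curvature-protein activation when the SV-AZ gap falls below 6 nm,
#' 5 us relaxation followed by a 100 us production run sampled every
#' 100 ns. `reduced_preset = TRUE` scales the geometry and durations to a
#' desk-size run (20 nm SV, 60 nm patch, 0.3 + 2 us) used by the test
#' suite; the timestep is kept at 0.1 ns.
#'
#' The simulator is reduced-fidelity by design: isotropic Stokes mobilities
#' replace hydrodynamic coupling, and the patch has a fixed area (no
#' barostat).
#'
#' @param timestep_ns integration step (0.1).
#' @param viscosity_cP cytosolic viscosity (2.21).
#' @param bending_rigidity_J membrane bending rigidity (0.8e-19 J).
#' @param sv_outer_diameter_nm,patch_side_nm geometry.
#' @param curvature_trigger_gap_nm gap that activates curvature proteins.
#' @param relax_time_us,run_time_us,sampling_interval_ns schedule.
#' @param curvature_protein_copies copies of curvature-inducing proteins.
#' @param v_snare_count,t_snare_count SNARE chains on SV / patch.
#' @param tether_count tethers formed between SV and patch at start.
#' @param temperature_K temperature (310).
#' @param mesh_nm target mesh spacing (2).
#' @param membrane_thickness_nm leaflet pair separation (4).
#' @param preferred_curvature_nm preferred curvature radius of active
#'   protein masks (25 nm, curving the AZ toward the SV).
#' @param seed RNG seed.
#' @param reduced_preset desk-scale preset flag.
#' @param ... expert overrides of interaction constants (k_edge, k_thick,
#'   k_volume, k_rep, rep_cut, snare_eps, snare_rc, k_tether, tether_kang,
#'   particle_radius_nm, initial_gap_nm, mc_every_steps).
#' @return a `sim_config` list.
#' @export
sim_config <- function(timestep_ns = 0.1,
                       viscosity_cP = 2.21,
                       bending_rigidity_J = 0.8e-19,
                       sv_outer_diameter_nm = 42.5,
                       patch_side_nm = 180,
                       curvature_trigger_gap_nm = 6,
                       relax_time_us = 5,
                       run_time_us = 100,
                       sampling_interval_ns = 100,
                       curvature_protein_copies = 0,
                       v_snare_count = 15,
                       t_snare_count = 15,
                       tether_count = 5,
                       temperature_K = 310,
                       mesh_nm = 2,
                       membrane_thickness_nm = 4,
                       preferred_curvature_nm = 25,
                       seed = 1L,
                       reduced_preset = FALSE,
                       ...) {
  cfg <- c(as.list(environment()), list(...))
  if (reduced_preset) {
    cfg$sv_outer_diameter_nm <- 20
    cfg$patch_side_nm <- 60
    cfg$relax_time_us <- 0.1
    cfg$run_time_us <- 1
    cfg$sampling_interval_ns <- 10
    # the explicit overdamped integrator is only stable below ~0.02 ns at
    # this mesh and rigidity; see the methods vignette
    cfg$timestep_ns <- 0.01
  }
  defaults <- list(k_edge = 25, k_thick = 10, k_volume = 2e6, k_rep = 50,
                   rep_cut = 2, snare_eps = 8, snare_rc = 2.5,
                   k_tether = 50, tether_kang = 1500,
                   particle_radius_nm = 1, initial_gap_nm = 12,
                   protein_bead_heights_nm = c(1.5, 3),
                   mc_every_steps = 200)
  for (f in names(defaults))
    if (is.null(cfg[[f]])) cfg[[f]] <- defaults[[f]]
  num <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  pos_req <- setdiff(names(num), c("curvature_protein_copies", "seed"))
  if (any(num[pos_req] <= 0))
    abort(paste0("parameter must be positive: ",
                 paste(pos_req[num[pos_req] <= 0], collapse = ", ")))
  if (cfg$curvature_protein_copies < 0) abort("copies must be >= 0")
  structure(cfg, class = "sim_config")
}

# kT in pN nm; kappa in pN nm; viscosity in pN ns / nm^2
.kT <- function(cfg) 1.380649e-23 * cfg$temperature_K * 1e21
.kappa <- function(cfg) cfg$bending_rigidity_J * 1e21
.eta <- function(cfg) cfg$viscosity_cP

#' Icosphere triangulation
#'
#' Subdivided icosahedron projected onto a sphere; subdivision depth is
#' chosen so the edge length does not exceed `target_edge_nm`.
#'
#' @param radius_nm sphere radius.
#' @param target_edge_nm maximal edge length.
#' @return list with `vertices` (n x 3), `faces` (m x 3, 1-based, outward
#'   oriented).
#' @export
icosphere <- function(radius_nm, target_edge_nm = 2) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11),
             c(1, 11, 12), c(2, 6, 10), c(6, 12, 5), c(12, 11, 3),
             c(11, 8, 7), c(8, 2, 9), c(4, 10, 5), c(4, 5, 3),
             c(4, 3, 7), c(4, 7, 9), c(4, 9, 10), c(5, 10, 6),
             c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  subdiv <- max(0L, ceiling(log2(1.0515 * radius_nm / target_edge_nm)))
  for (s in seq_len(subdiv)) {
    mid <- new.env(hash = TRUE, parent = emptyenv())
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid[[key]]
      if (!is.null(id)) return(id)
      m <- v[a, ] + v[b, ]
      v <<- rbind(v, m / sqrt(sum(m^2)))
      mid[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4 * i - 3, ] <- c(a, ab, ca)
      nf[4 * i - 2, ] <- c(b, bc, ab)
      nf[4 * i - 1, ] <- c(cc, ca, bc)
      nf[4 * i, ] <- c(ab, bc, ca)
    }
    f <- nf
  }
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], ]
    nrm <- c(tri[2, ] - tri[1, ], 0)[1:3]
    e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
             e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
    if (sum(nrm * colMeans(tri)) < 0) f[i, ] <- f[i, c(1, 3, 2)]
  }
  list(vertices = v * radius_nm, faces = f)
}

# periodic triangulated patch; returns vertices, faces (1-based), box
patch_mesh <- function(side_nm, spacing_nm = 2) {
  nx <- max(4L, round(side_nm / spacing_nm))
  dy <- spacing_nm * sqrt(3) / 2
  ny <- max(4L, 2L * round(side_nm / dy / 2))
  dx <- side_nm / nx
  dy <- side_nm / ny
  vid <- function(i, j) (j %% ny) * nx + (i %% nx) + 1L
  verts <- matrix(0, nx * ny, 3)
  for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    verts[vid(i, j), 1:2] <- c((i + 0.5 * (j %% 2)) * dx, j * dy)
  }
  faces <- matrix(0L, 2 * nx * ny, 3)
  k <- 0L
  for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    j2 <- j + 1L
    if (j %% 2 == 0) {
      faces[k + 1L, ] <- c(vid(i, j), vid(i + 1, j), vid(i, j2))
      faces[k + 2L, ] <- c(vid(i + 1, j), vid(i + 1, j2), vid(i, j2))
    } else {
      faces[k + 1L, ] <- c(vid(i, j), vid(i + 1, j), vid(i + 1, j2))
      faces[k + 2L, ] <- c(vid(i, j), vid(i + 1, j2), vid(i, j2))
    }
    k <- k + 2L
  }
  list(vertices = verts, faces = faces, box = c(side_nm, side_nm))
}

# edges and dihedral quads (torsion order k,i,j,l; edge i-j) from faces
mesh_topology <- function(faces) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edge_env <- new.env(hash = TRUE, parent = emptyenv())
  edges <- matrix(0L, 0, 2)
  quads <- matrix(0L, 0, 4)
  ek <- character(0)
  el <- list()
  for (i in seq_len(nrow(faces))) {
    tri <- faces[i, ]
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- tri[e[1]]; b <- tri[e[2]]; opp <- tri[-e][1]
      k <- key(a, b)
      prev <- edge_env[[k]]
      if (is.null(prev)) {
        edge_env[[k]] <- c(a, b, opp)
      } else {
        quads <- rbind(quads, c(prev[3], prev[1], prev[2], opp))
        edges <- rbind(edges, c(a, b))
      }
    }
  }
  list(edges = edges, quads = quads)
}

#' Build the initial docking system
#'
#' Assembles the particle state: the SV as a two-leaflet icosphere above the
#' centre of a periodic two-leaflet membrane patch, tether rods between
#' random SV bottom vertices and patch anchors, register-matched v-/t-SNARE
#' bead chains, and curvature-protein particles tagged to random patch
#' vertices under the SV. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a `cg_system` list (positions, topology, interaction tables).
#' @export
build_system <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  kap <- .kappa(cfg)
  lambda_edge <- 2 * sqrt(3) * kap
  thick <- cfg$membrane_thickness_nm
  R <- cfg$sv_outer_diameter_nm / 2

  ico <- icosphere(R, cfg$mesh_nm)
  pm <- patch_mesh(cfg$patch_side_nm, cfg$mesh_nm)
  n_sv <- nrow(ico$vertices)
  n_pa <- nrow(pm$vertices)
  if (cfg$curvature_protein_copies > 0.25 * n_pa)
    abort("over-dense curvature-protein placement")

  cx <- pm$box[1] / 2; cy <- pm$box[2] / 2
  z0 <- cfg$initial_gap_nm + R
  sv_outer <- sweep(ico$vertices, 2, c(cx, cy, z0), "+")
  sv_inner <- sweep(ico$vertices * ((R - thick) / R), 2,
                    c(cx, cy, z0), "+")
  pa_outer <- pm$vertices
  pa_inner <- sweep(pm$vertices, 2, c(0, 0, -thick), "+")

  pos <- rbind(sv_outer, sv_inner, pa_outer, pa_inner)
  comp <- c(rep(1L, n_sv), rep(2L, n_sv), rep(3L, n_pa), rep(4L, n_pa))
  body <- c(rep(1L, 2 * n_sv), rep(2L, 2 * n_pa))
  i_sv_out <- seq_len(n_sv)
  i_pa_out <- 2 * n_sv + seq_len(n_pa)

  topo_sv <- mesh_topology(ico$faces)
  topo_pa <- mesh_topology(pm$faces)

  bond <- function(i, j, k, type, posm = pos, box = pm$box) {
    d <- posm[i, , drop = FALSE] - posm[j, , drop = FALSE]
    d[, 1] <- d[, 1] - box[1] * round(d[, 1] / box[1])
    d[, 2] <- d[, 2] - box[2] * round(d[, 2] / box[2])
    cbind(i - 1L, j - 1L, sqrt(rowSums(d^2)), k, type)
  }
  bonds <- NULL
  e <- topo_sv$edges
  bonds <- rbind(bonds,
    bond(e[, 1], e[, 2], cfg$k_edge, 1),
    bond(e[, 1] + n_sv, e[, 2] + n_sv, cfg$k_edge, 1),
    bond(i_sv_out, i_sv_out + n_sv, cfg$k_thick, 2))
  e <- topo_pa$edges
  bonds <- rbind(bonds,
    bond(e[, 1] + 2L * n_sv, e[, 2] + 2L * n_sv, cfg$k_edge, 1),
    bond(e[, 1] + 2L * n_sv + n_pa, e[, 2] + 2L * n_sv + n_pa,
         cfg$k_edge, 1),
    bond(i_pa_out, i_pa_out + n_pa, cfg$k_thick, 2))

  quads <- rbind(topo_sv$quads, topo_pa$quads + 2L * n_sv)
  lambda <- rep(lambda_edge, nrow(quads))
  theta0 <- rep(0, nrow(quads))

  # tethers: SV bottom vertices to nearby patch anchors
  bottom <- order(sv_outer[, 3])[seq_len(max(20, cfg$tether_count * 4))]
  t_sv <- sample(bottom, cfg$tether_count)
  lateral <- sqrt((pa_outer[, 1] - cx)^2 + (pa_outer[, 2] - cy)^2)
  near <- which(lateral < 1.2 * R + 5)
  t_anchor <- sample(near, cfg$tether_count)
  bonds <- rbind(bonds,
    bond(t_sv, 2L * n_sv + t_anchor, cfg$k_tether, 4))

  # SNARE chains: 4 beads each, spaced 1.2 nm along the membrane normal
  mk_chain <- function(base_xyz, direction, n_chain, comp_code, body_code) {
    if (n_chain == 0) {
      return(list(pos = matrix(0, 0, 3), comp = integer(0),
                  body = integer(0), bonds = NULL, first = integer(0)))
    }
    ppos <- NULL; pcomp <- integer(0); pbody <- integer(0)
    pb <- NULL; firsts <- integer(0)
    for (ch in seq_len(n_chain)) {
      beads <- t(vapply(1:4, function(m)
        base_xyz[ch, ] + direction[ch, ] * (0.6 + 1.2 * (m - 1)),
        numeric(3)))
      firsts <- c(firsts, nrow(ppos %||% matrix(0, 0, 3)) + 1L)
      ppos <- rbind(ppos, beads)
      pcomp <- c(pcomp, rep(comp_code, 4L))
      pbody <- c(pbody, rep(body_code, 4L))
    }
    list(pos = ppos, comp = pcomp, body = pbody, first = firsts)
  }
  v_base_id <- sample(bottom, cfg$v_snare_count, replace = TRUE)
  v_dir <- -sv_outer[v_base_id, , drop = FALSE]
  v_dir <- sweep(v_dir, 2, c(-cx, -cy, -z0), "+")
  v_dir <- v_dir / sqrt(rowSums(v_dir^2))
  vch <- mk_chain(sv_outer[v_base_id, , drop = FALSE], v_dir,
                  cfg$v_snare_count, 5L, 1L)
  t_base_id <- sample(near, cfg$t_snare_count, replace = TRUE)
  t_dir <- matrix(rep(c(0, 0, 1), length(t_base_id)), ncol = 3,
                  byrow = TRUE)
  tch <- mk_chain(pa_outer[t_base_id, , drop = FALSE], t_dir,
                  cfg$t_snare_count, 6L, 2L)

  off_v <- nrow(pos)
  pos <- rbind(pos, vch$pos)
  off_t <- nrow(pos)
  pos <- rbind(pos, tch$pos)
  comp <- c(comp, vch$comp, tch$comp)
  body <- c(body, vch$body, tch$body)

  chain_bonds <- function(firsts, offset, anchors) {
    out <- NULL
    for (ci in seq_along(firsts)) {
      ids <- offset + firsts[ci] + 0:3
      out <- rbind(out,
        cbind(anchors[ci] - 1L, ids[1] - 1L, 0.6, cfg$k_edge, 3),
        cbind(ids[-4] - 1L, ids[-1] - 1L, 1.2, cfg$k_edge, 3))
    }
    out
  }
  if (cfg$v_snare_count > 0)
    bonds <- rbind(bonds, chain_bonds(vch$first, off_v, v_base_id))
  if (cfg$t_snare_count > 0)
    bonds <- rbind(bonds, chain_bonds(tch$first, off_t,
                                      2L * n_sv + t_base_id))

  # register-matched attraction: bead m of any v chain <-> bead m of any t
  snare_pairs <- matrix(0L, 0, 2)
  if (cfg$v_snare_count > 0 && cfg$t_snare_count > 0) {
    for (m in 1:4) {
      vi <- off_v + vch$first + (m - 1L)
      ti <- off_t + tch$first + (m - 1L)
      snare_pairs <- rbind(snare_pairs,
                           as.matrix(expand.grid(vi - 1L, ti - 1L)))
    }
  }

  # curvature proteins: bead above a host patch vertex under the SV
  prot_host <- integer(0)
  protein_quads <- list()
  if (cfg$curvature_protein_copies > 0) {
    under <- which(lateral < R + 4)
    prot_host <- sample(under, cfg$curvature_protein_copies)
    hts <- cfg$protein_bead_heights_nm
    nb <- length(hts)
    off_p <- nrow(pos)
    for (pi in seq_along(prot_host)) {
      ppos <- matrix(rep(pa_outer[prot_host[pi], ], nb), ncol = 3,
                     byrow = TRUE)
      ppos[, 3] <- ppos[, 3] + hts
      pos <- rbind(pos, ppos)
      comp <- c(comp, rep(7L, nb))
      body <- c(body, rep(5L, nb))
      ids <- off_p + (pi - 1L) * nb + seq_len(nb)
      bonds <- rbind(bonds,
        cbind(2L * n_sv + prot_host[pi] - 1L, ids[1] - 1L, hts[1],
              cfg$k_edge, 5),
        if (nb > 1) cbind(ids[-nb] - 1L, ids[-1] - 1L, diff(hts),
                          cfg$k_edge, 5))
    }
    # dihedrals whose four vertices touch the host vertex (patch mesh)
    pa_quads_global <- topo_pa$quads + 2L * n_sv
    for (pi in seq_along(prot_host)) {
      host_global <- 2L * n_sv + prot_host[pi]
      qidx <- which(apply(pa_quads_global == host_global, 1, any))
      protein_quads[[pi]] <- nrow(topo_sv$quads) + qidx - 1L  # 0-based
    }
  }
  theta0_active <- rep(0, nrow(quads))
  # convex-toward-the-normal reads as negative dihedral deviation in this
  # winding; active masks prefer the patch to bulge upward, toward the SV
  theta_pref <- -cfg$mesh_nm / cfg$preferred_curvature_nm
  for (pi in seq_along(protein_quads))
    theta0_active[protein_quads[[pi]] + 1L] <- theta_pref

  V0 <- NULL
  sysr <- list(
    pos = pos, comp = as.integer(comp), body = as.integer(body),
    bonds = bonds[, 1:5, drop = FALSE],
    quads = matrix(as.integer(quads - 1L), ncol = 4),
    lambda = lambda, theta0 = theta0,
    faces = matrix(as.integer(ico$faces - 1L), ncol = 3),
    V0 = 0, kV = cfg$k_volume,
    rep_k = cfg$k_rep, rep_cut = cfg$rep_cut,
    snare_pairs = matrix(as.integer(snare_pairs), ncol = 2),
    snare_eps = cfg$snare_eps, snare_rc = cfg$snare_rc,
    tethers = matrix(as.integer(
      c(t_sv - 1L, 2L * n_sv + t_anchor - 1L)), ncol = 2),
    tether_kang = cfg$tether_kang, tether_active = FALSE,
    box = pm$box, periodic = TRUE,
    theta0_active = theta0_active,
    protein_quads = protein_quads,
    mask_state = rep(FALSE, length(protein_quads)),
    n_sv = n_sv, n_pa = n_pa,
    i_sv_out = i_sv_out, i_pa_out = i_pa_out,
    config = cfg)
  sysr$V0 <- cpp_sv_volume(sysr)
  if (!is.finite(cpp_cg_energy(sysr)[["total"]]))
    abort("non-finite initial energy")
  class(sysr) <- "cg_system"
  sysr
}

#' @export
print.cg_system <- function(x, ...) {
  cat("<cg_system>", nrow(x$pos), "particles (SV", x$n_sv, "x2, patch",
      x$n_pa, "x2),", nrow(x$bonds), "bonds,", nrow(x$quads),
      "dihedrals,", length(x$protein_quads), "curvature proteins\n")
  invisible(x)
}

#' Total energy of a docking system
#'
#' @param state a `cg_system`.
#' @return named vector: stretching, bending, volume, repulsion, snare,
#'   tether_angle, total (pN nm).
#' @export
total_energy <- function(state) {
  stopifnot(inherits(state, "cg_system"))
  cpp_cg_energy(state)
}

#' Advance the system by Brownian-dynamics steps
#'
#' Overdamped integration with isotropic Stokes mobilities and
#' fluctuation-dissipation-consistent thermal noise. Deterministic given
#' the R RNG state (set a seed before calling). A displacement larger than
#' 1 nm in a single step aborts with an instability diagnostic.
#'
#' @param state a `cg_system`.
#' @param cfg its [sim_config()] (defaults to the config stored in state).
#' @param n_steps number of steps (default 1).
#' @param temperature_K override temperature (0 = deterministic descent).
#' @return the advanced `cg_system`.
#' @export
step_bd <- function(state, cfg = state$config, n_steps = 1,
                    temperature_K = cfg$temperature_K) {
  kT <- 1.380649e-23 * temperature_K * 1e21
  mob <- rep(1 / (6 * pi * .eta(cfg) * cfg$particle_radius_nm),
             nrow(state$pos))
  res <- cpp_cg_run(state, as.integer(n_steps), cfg$timestep_ns, mob,
                    kT, 0L, 0L, state$protein_quads, state$theta0_active,
                    state$mask_state, FALSE, 1.0, 0L)
  if (res$unstable)
    abort(paste0("BD unstable: displacement ", signif(res$max_disp, 3),
                 " nm in one step; reduce the timestep"))
  state$pos <- res$pos
  state
}

#' Monte Carlo update of the curvature-protein force-field masks
#'
#' One Metropolis sweep over the curvature proteins: each proposal toggles
#' one protein's mask (active masks impose the preferred signed curvature
#' on the surrounding membrane dihedrals); acceptance follows the Boltzmann
#' factor of the bending-energy change, so the chain satisfies detailed
#' balance with respect to [total_energy()].
#'
#' @param state a `cg_system`.
#' @param cfg its [sim_config()].
#' @param n_sweeps number of sweeps (default 1).
#' @return the updated `cg_system`; attribute `mc` holds proposal/accept
#'   counts split by toggle direction.
#' @export
mc_curvature_update <- function(state, cfg = state$config, n_sweeps = 1) {
  if (length(state$protein_quads) == 0) return(state)
  kT <- .kT(cfg)
  mob <- rep(1, nrow(state$pos))
  res <- cpp_cg_run(state, 0L, cfg$timestep_ns, mob, kT, 0L, 0L,
                    state$protein_quads, state$theta0_active,
                    state$mask_state, TRUE, 1.0, as.integer(n_sweeps))
  state$mask_state <- res$mask_state
  state$theta0[unlist(state$protein_quads) + 1L] <- 0
  for (pi in which(state$mask_state))
    state$theta0[state$protein_quads[[pi]] + 1L] <-
      state$theta0_active[state$protein_quads[[pi]] + 1L]
  attr(state, "mc") <- res$mc
  state
}

# vertical SV-patch gap: lowest SV outer particle vs the local patch
# surface below it (mean patch-outer height within 5 nm laterally - an
# unbiased local surface estimate - falling back to the patch mean)
sv_patch_gap <- function(state) {
  svz <- state$pos[state$i_sv_out, 3]
  i_low <- state$i_sv_out[which.min(svz)]
  pxy <- state$pos[state$i_pa_out, 1:2, drop = FALSE]
  lat <- sqrt((pxy[, 1] - state$pos[i_low, 1])^2 +
              (pxy[, 2] - state$pos[i_low, 2])^2)
  below <- lat < 5
  ztop <- if (any(below)) mean(state$pos[state$i_pa_out[below], 3])
          else mean(state$pos[state$i_pa_out, 3])
  min(svz) - ztop
}

#' Run the docking protocol
#'
#' Relaxation (tether torque off) -> tether activation -> curvature-mask
#' activation when the SV-AZ gap first falls below the trigger -> run to
#' the configured end time. The gap is sampled at the configured interval.
#'
#' @param cfg a [sim_config()].
#' @param system optionally a pre-built [build_system()] state.
#' @param stop_at_trigger end the run once the curvature trigger fires
#'   (useful when only the time to trigger is of interest).
#' @return a `docking_trajectory`: `gap_series` tibble (time_us, gap_nm,
#'   phase), `events` tibble (tether activation, trigger crossing),
#'   `final_state`, `config`.
#' @export
run_docking <- function(cfg, system = NULL, stop_at_trigger = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  state <- if (is.null(system)) build_system(cfg) else system
  set.seed(cfg$seed + 1L)
  kT <- .kT(cfg)
  mob <- rep(1 / (6 * pi * .eta(cfg) * cfg$particle_radius_nm),
             nrow(state$pos))
  dt <- cfg$timestep_ns
  chunk_steps <- max(1L, round(cfg$sampling_interval_ns / dt))
  n_relax <- max(1L, round(cfg$relax_time_us * 1000 / dt / chunk_steps))
  n_run <- max(1L, round(cfg$run_time_us * 1000 / dt / chunk_steps))

  gap <- numeric(0); tt <- numeric(0); phase <- character(0)
  events <- list()
  t_now <- 0
  triggered <- FALSE
  run_chunk <- function(masks_on) {
    res <- cpp_cg_run(state, chunk_steps, dt, mob, kT, 0L,
                      as.integer(cfg$mc_every_steps),
                      state$protein_quads, state$theta0_active,
                      state$mask_state, masks_on, 1.0, 0L)
    if (res$unstable)
      abort(paste0("BD unstable at t = ", signif(t_now, 4),
                   " us: displacement ", signif(res$max_disp, 3),
                   " nm in one step; reduce the timestep"))
    state$pos <<- res$pos
    state$mask_state <<- res$mask_state
    t_now <<- t_now + chunk_steps * dt / 1000
  }

  state$tether_active <- FALSE
  for (i in seq_len(n_relax)) {
    run_chunk(FALSE)
    gap <- c(gap, sv_patch_gap(state)); tt <- c(tt, t_now)
    phase <- c(phase, "relax")
  }
  state$tether_active <- TRUE
  events$tether <- tibble::tibble(event = "tether_activation",
                                  time_us = t_now)
  for (i in seq_len(n_run)) {
    run_chunk(triggered)
    g <- sv_patch_gap(state)
    if (!triggered && g < cfg$curvature_trigger_gap_nm) {
      triggered <- TRUE
      events$trigger <- tibble::tibble(event = "curvature_trigger",
                                       time_us = t_now)
    }
    gap <- c(gap, g); tt <- c(tt, t_now)
    phase <- c(phase, if (triggered) "curvature" else "approach")
    if (triggered && stop_at_trigger) break
  }
  structure(list(
    gap_series = tibble::tibble(time_us = tt, gap_nm = gap, phase = phase),
    events = dplyr::bind_rows(events),
    triggered = triggered,
    time_to_trigger_us = if (triggered)
      events$trigger$time_us - events$tether$time_us else NA_real_,
    final_state = state, config = cfg),
    class = "docking_trajectory")
}

#' @export
print.docking_trajectory <- function(x, ...) {
  cat("<docking_trajectory>", nrow(x$gap_series), "samples; trigger",
      if (x$triggered) sprintf("at %.3f us", x$time_to_trigger_us)
      else "not reached", "\n")
  invisible(x)
}
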