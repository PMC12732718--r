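#' Parameters for the synthetic fusion-trajectory generator
#'
#' The generator is kinematic, not physical: it carries known statistical
#' structure (fusion-onset time, per-molecule leaflet classes, cluster
#' membership, tail-orientation order) through real coordinate/trajectory
#' formats so every analysis stage can be tested without running
#' simulations. Defaults reproduce the study conditions: a 100-lipid
#' nanodroplet at IL:CHOL:DSPC 50:40:10, endosomal membranes of 192/94/162
#' (EEM) or 292/76/80 (LEM) POPC/DOPE/CHOL or 360/90 POPC/POPS (SLB),
#' 2000 ns of frames at 200 ps spacing, an initial droplet-membrane gap of
#' about 1 nm, and occupancy probabilities representative of the reported
#' migration tables (the 50% protonated case: protonated outer 0.29 /
#' midplane 0.46, deprotonated outer 0.04 / midplane 0.94).
#'
#' @param seed integer RNG seed (same seed, same trajectory and ground
#'   truth, bit for bit).
#' @param il ionizable lipid: "ALC-0315" (residues ALCP/ALCD, head-terminal
#'   bead OH) or "MC3" (residues MC3P/MC3D, head-terminal bead NC3).
#' @param membrane membrane type: "EEM", "LEM" or "SLB".
#' @param protonated_percent percent of ionizable lipids protonated; must
#'   lie on the 10% grid.
#' @param frames,spacing_ps number of frames and frame spacing (ps).
#' @param onset_ps planted fusion-onset time (ps); snapped to the frame grid.
#' @param gap_nm initial minimum droplet-membrane distance (nm).
#' @param box length-3 box (nm); default depends on the membrane type.
#' @param membrane_counts named lipid counts overriding the membrane-type
#'   default.
#' @param lnd_composition named counts `c(IL=, CHOL=, DSPC=)`.
#' @param jitter positional jitter SD (nm) for membrane lattice sites,
#'   truncated at 2 SD so the planted classification margins stay
#'   guaranteed.
#' @param class_probs list with `IL_PROTONATED` and `IL_DEPROTONATED`
#'   probability vectors `c(inner=, outer=, midplane=)`, each summing to 1.
#' @param retained named counts `c(protonated=, deprotonated=, other=)` of
#'   molecules kept in the surviving post-fusion cluster; defaults scale
#'   with the species counts.
#' @param order_w named aligned-population weights (planted P2) per chain
#'   group: `il_protonated`, `il_deprotonated`, `popc`, `membrane_other`,
#'   `dspc`.
#' @param deepest_species which species supplies the deepest (first
#'   entering) molecule before onset: "IL", "CHOL" or "DSPC".
#' @param second_species optionally plant a second-deepest molecule of this
#'   species, e.g. a cholesterol-first scenario with the best ionizable
#'   lipid at rank 2.
#' @param blip optional pre-onset negative excursion shorter than the
#'   persistence rule: `list(at_frac=, n_frames=, depth=)`, positioned at
#'   `at_frac` of the way to the onset frame.
#' @param tail_resample "per_frame" (tail orientations redrawn each frame)
#'   or "static".
#' @param class_resample "per_molecule" (one leaflet class per molecule for
#'   the whole post-fusion window, mirroring single flip-flop events) or
#'   "per_frame" (stress mode; cluster ground truth is still guaranteed
#'   because isolation is enforced in the xy plane only).
#' @return list of class `synthetic_params`.
#' @export
synthetic_params <- function(seed = 1L,
                             il = c("ALC-0315", "MC3"),
                             membrane = c("EEM", "LEM", "SLB"),
                             protonated_percent = 50,
                             frames = 10001L, spacing_ps = 200,
                             onset_ps = 4e5, gap_nm = 1.0,
                             box = NULL, membrane_counts = NULL,
                             lnd_composition = c(IL = 50, CHOL = 40, DSPC = 10),
                             jitter = 0.05,
                             class_probs = list(
                               IL_PROTONATED = c(inner = 0.25, outer = 0.29, midplane = 0.46),
                               IL_DEPROTONATED = c(inner = 0.02, outer = 0.04, midplane = 0.94)),
                             retained = NULL,
                             order_w = c(il_protonated = 0.30, il_deprotonated = 0.05,
                                         popc = 0.60, membrane_other = 0.50, dspc = 0.30),
                             deepest_species = "IL", second_species = NULL,
                             blip = NULL,
                             tail_resample = c("per_frame", "static"),
                             class_resample = c("per_molecule", "per_frame")) {
  il <- match.arg(il)
  membrane <- match.arg(membrane)
  tail_resample <- match.arg(tail_resample)
  class_resample <- match.arg(class_resample)
  stopifnot(frames >= 2L, spacing_ps > 0, gap_nm > 0, onset_ps > 0)
  if (protonated_percent %% 10 != 0 || protonated_percent < 0 || protonated_percent > 100) {
    stop("protonated_percent must lie on the 10% grid in [0, 100]", call. = FALSE)
  }
  if (is.null(box)) {
    box <- switch(membrane, EEM = c(10.7, 10.7, 25.0), LEM = c(11.5, 11.5, 25.0),
                  SLB = c(12.2, 12.2, 25.0))
  }
  check_box(box)
  if (is.null(membrane_counts)) {
    membrane_counts <- switch(membrane,
                              EEM = c(POPC = 192, DOPE = 94, CHOL = 162),
                              LEM = c(POPC = 292, DOPE = 76, CHOL = 80),
                              SLB = c(POPC = 360, POPS = 90))
  }
  stopifnot(all(membrane_counts > 0), "POPC" %in% names(membrane_counts))
  stopifnot(all(lnd_composition >= 0), lnd_composition["IL"] > 0)
  n_il <- unname(lnd_composition["IL"])
  n_prot <- round(n_il * protonated_percent / 100)
  n_deprot <- n_il - n_prot
  for (s in names(class_probs)) {
    p <- class_probs[[s]]
    if (!setequal(names(p), c("inner", "outer", "midplane")) ||
        abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      stop("class_probs$", s, " must be c(inner=, outer=, midplane=) summing to 1",
           call. = FALSE)
    }
  }
  n_other <- unname(lnd_composition["CHOL"] + lnd_composition["DSPC"])
  if (is.null(retained)) {
    retained <- c(protonated = round(0.2 * n_prot),
                  deprotonated = round(0.45 * n_deprot),
                  other = min(10, n_other))
  }
  if (!setequal(names(retained), c("protonated", "deprotonated", "other"))) {
    stop("retained must be named c(protonated=, deprotonated=, other=)", call. = FALSE)
  }
  if (retained[["protonated"]] > n_prot || retained[["deprotonated"]] > n_deprot ||
      retained[["other"]] > n_other) {
    stop(sprintf(
      "retained counts (%d, %d, %d) exceed species counts (%d protonated, %d deprotonated, %d other)",
      retained[["protonated"]], retained[["deprotonated"]], retained[["other"]],
      n_prot, n_deprot, n_other), call. = FALSE)
  }
  if (!is.null(blip)) {
    stopifnot(is.list(blip), !is.null(blip$at_frac), blip$at_frac > 0, blip$at_frac < 1)
    blip$n_frames <- as.integer(blip$n_frames %||% 2L)
    blip$depth <- blip$depth %||% 0.3
    if (blip$n_frames * spacing_ps >= 1000) {
      stop("blip length must stay below the 1 ns persistence window", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), il = il, membrane = membrane,
                 protonated_percent = protonated_percent,
                 n_prot = n_prot, n_deprot = n_deprot,
                 frames = as.integer(frames), spacing_ps = spacing_ps,
                 onset_ps = onset_ps, gap_nm = gap_nm, box = box,
                 membrane_counts = membrane_counts,
                 lnd_composition = lnd_composition, jitter = jitter,
                 class_probs = class_probs, retained = retained,
                 order_w = order_w, deepest_species = deepest_species,
                 second_species = second_species, blip = blip,
                 tail_resample = tail_resample, class_resample = class_resample),
            class = "synthetic_params")
}

# truncated gaussian jitter: never exceeds 2 SD, preserving the geometric
# margins the planted classifications rely on
.trunc_jitter <- function(n, sd) {
  if (sd <= 0 || n == 0L) return(rep(0, n))
  pmin(pmax(stats::rnorm(n, 0, sd), -2 * sd), 2 * sd)
}

.unit_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z * z))
  cbind(r * cos(phi), r * sin(phi), z)
}

# two-population chain directions: aligned with the (signed) normal with
# probability w, otherwise an isotropic random direction; the whole chain is
# rigid along the drawn direction, so every segment of the chain (bonds and
# non-consecutive vectors alike) carries the same planted P2 = w
.chain_dirs <- function(n, w, align_sign) {
  d <- .unit_sphere(n)
  al <- stats::runif(n) < w
  if (any(al)) {
    d[al, 1] <- 0
    d[al, 2] <- 0
    d[al, 3] <- align_sign[al]
  }
  d
}

# LND molecules are deliberately compact (chain bond 0.012 nm, fixed-bead
# offsets <= 0.05 nm) so a 1.5 nm xy lattice guarantees single-linkage
# isolation of dispersed molecules; membrane tails use a realistic 0.25 nm
# bond (membrane beads never enter the clustering)
.lnd_bond <- 0.012
.mem_bond <- 0.25

.lnd_templates <- list(
  ALC = list(beads = rbind(NC3 = c(0, 0, 0.04), OH = c(0.04, 0, 0.05),
                           GL1 = c(-0.04, 0, -0.02), GL2 = c(0.04, 0, -0.02)),
             chain_defs = list(list(origin = "GL1", beads = paste0("T", 1:5)),
                               list(origin = "GL2", beads = paste0("T", 6:10)))),
  MC3 = list(beads = rbind(NC3 = c(0, 0, 0.04),
                           CAo = c(-0.04, 0, -0.02), CBo = c(0.04, 0, -0.02)),
             chain_defs = list(list(origin = "CAo", beads = paste0("CA", 1:5)),
                               list(origin = "CBo", beads = paste0("CB", 1:5)))),
  DSPC = list(beads = rbind(NC3 = c(0, 0, 0.05), PO4 = c(0, 0, 0.02),
                            GL1 = c(-0.04, 0, -0.01), GL2 = c(0.04, 0, -0.01)),
              chain_defs = list(list(origin = "GL1", beads = c("C1A", "C2A")),
                                list(origin = "GL2", beads = c("C1B", "C2B")))),
  CHOL = list(beads = rbind(ROH = c(0, 0, 0.03), R1 = c(0, 0, 0),
                            R2 = c(0.03, 0, -0.02), C1 = c(0, 0.03, -0.03)),
              chain_defs = list())
)

.mem_head_bead <- c(POPC = "NC3", DOPE = "NH3", POPS = "CNO")

# internal accumulator for atoms / base coordinates / batched chain groups
.new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$atoms <- list()
  env$xyz <- list()
  env$chains <- list()
  env$nrow <- 0L
  env
}

.add_beads <- function(b, molecule_id, molecule_name, bead_name, xyz) {
  b$atoms[[length(b$atoms) + 1L]] <- data.frame(
    molecule_id = molecule_id, molecule_name = molecule_name,
    bead_name = bead_name, stringsAsFactors = FALSE)
  b$xyz[[length(b$xyz) + 1L]] <- xyz
  idx <- b$nrow + seq_along(bead_name)
  b$nrow <- b$nrow + length(bead_name)
  idx
}

.add_chain_group <- function(b, origin_idx, bead_idx, w_key, bond, align_sign) {
  b$chains[[length(b$chains) + 1L]] <- list(
    origin_idx = origin_idx, bead_idx = bead_idx, w_key = w_key,
    bond = bond, align_sign = align_sign)
}

.builder_tables <- function(b) {
  atoms <- do.call(rbind, b$atoms)
  xyz <- do.call(rbind, b$xyz)
  # make molecules contiguous (GRO convention); stable order keeps fixed
  # beads ahead of chain beads within each molecule
  ord <- order(atoms$molecule_id)
  inv <- integer(nrow(atoms))
  inv[ord] <- seq_len(nrow(atoms))
  chains <- lapply(b$chains, function(g) {
    g$origin_idx <- inv[g$origin_idx]
    g$bead_idx <- matrix(inv[g$bead_idx], nrow = nrow(g$bead_idx))
    g
  })
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  atoms$molecule_id <- as.integer(atoms$molecule_id)
  list(atoms = atoms, xyz = xyz[ord, , drop = FALSE], chains = chains)
}

# draw fresh chain directions and place all chain beads for one frame
.fill_chains <- function(base_xyz, chains, order_w) {
  for (g in chains) {
    n <- length(g$origin_idx)
    dirs <- .chain_dirs(n, order_w[[g$w_key]], g$align_sign)
    org <- base_xyz[g$origin_idx, , drop = FALSE]
    for (j in seq_len(ncol(g$bead_idx))) {
      base_xyz[g$bead_idx[, j], ] <- org + j * g$bond * dirs
    }
  }
  base_xyz
}

# place one batch of identical molecules: fixed template beads at jittered
# anchors (z offsets flipped by `orient`), chains registered for later fill
.place_batch <- function(b, tpl, ids, name, anchors, orient, w_key, bond) {
  nm <- length(ids)
  off <- tpl$beads
  nb <- nrow(off)
  xyz <- cbind(rep(anchors[, 1], each = nb) + off[, 1],
               rep(anchors[, 2], each = nb) + off[, 2],
               rep(anchors[, 3], each = nb) + rep(orient, each = nb) * off[, 3])
  fixed_idx <- .add_beads(b, rep(ids, each = nb), rep(name, nm * nb),
                          rep(rownames(off), nm), xyz)
  fixed_mat <- matrix(fixed_idx, nrow = nm, byrow = TRUE)
  colnames(fixed_mat) <- rownames(off)
  for (ch in tpl$chain_defs) {
    nc <- length(ch$beads)
    cb <- .add_beads(b, rep(ids, each = nc), rep(name, nm * nc),
                     rep(ch$beads, nm), matrix(NA_real_, nm * nc, 3L))
    .add_chain_group(b, fixed_mat[, ch$origin], matrix(cb, nrow = nm, byrow = TRUE),
                     w_key, bond, if (length(orient) == 1L) rep(-orient, nm) else -orient)
  }
  fixed_mat
}

#' Build a synthetic endosomal membrane bilayer
#'
#' Two leaflets with PO4 (head) sheets at `membrane-centre +/- 2 nm` and
#' truncated-Gaussian positional jitter; tails point toward the midplane.
#' Each lipid species is laid out on its own near-uniform lattice per
#' leaflet (species counts split evenly between leaflets), which keeps the
#' POPC phosphate sheet dense everywhere - the property the 1.2 nm leaflet
#' classification margins rely on. The ledger records every lipid's leaflet.
#'
#' @param params a [synthetic_params()] object.
#' @return list with `frame` (a [cg_frame] with tails drawn once),
#'   `ledger` (data.frame `molecule_id`, `molecule_name`, `leaflet`),
#'   `planes` (named z of the two PO4 sheets).
#' @examples
#' m <- make_membrane(synthetic_params(seed = 7))
#' nrow(m$ledger)  # 448 lipids for the EEM composition
#' @export
make_membrane <- function(params) {
  set.seed(params$seed)
  built <- .build_membrane(params)
  xyz <- .fill_chains(built$xyz, built$chains, params$order_w)
  list(frame = cg_frame(built$atoms, xyz, params$box, 0),
       ledger = built$ledger, planes = built$planes)
}

.mem_template_for <- function(sp_name) {
  if (sp_name == "CHOL") {
    list(beads = rbind(ROH = c(0, 0, 0), R1 = c(0, 0, -0.3), R2 = c(0.05, 0, -0.5),
                       C1 = c(0, 0, -0.7)),
         chain_defs = list())
  } else {
    hb <- .mem_head_bead[[sp_name]]
    beads <- rbind(c(0, 0, 0.20), PO4 = c(0, 0, 0), GL1 = c(-0.06, 0, -0.25),
                   GL2 = c(0.06, 0, -0.25))
    rownames(beads)[1] <- hb
    list(beads = beads,
         chain_defs = list(list(origin = "GL1", beads = c("C1A", "C2A")),
                           list(origin = "GL2", beads = c("C1B", "C2B"))))
  }
}

.build_membrane <- function(p, first_id = 1L) {
  counts <- p$membrane_counts
  mid <- p$box[3] / 2
  planes <- c(upper = mid + 2, lower = mid - 2)
  b <- .new_builder()
  ledger <- list()
  mol_id <- first_id - 1L
  for (leaf in c("upper", "lower")) {
    s <- if (leaf == "upper") 1 else -1
    for (k in seq_along(counts)) {
      sp_name <- names(counts)[k]
      nsp <- if (leaf == "upper") ceiling(counts[[k]] / 2) else floor(counts[[k]] / 2)
      if (nsp == 0L) next
      # per-species lattice: keeps every species (POPC in particular)
      # near-uniformly spread over the leaflet
      nx <- ceiling(sqrt(nsp))
      if (min(p$box[1], p$box[2]) / nx < 0.6) {
        stop(sprintf("box too small for %d %s per leaflet (lattice spacing %.2f nm < 0.6 nm)",
                     nsp, sp_name, min(p$box[1], p$box[2]) / nx), call. = FALSE)
      }
      phase <- 0.11 * k    # offset species lattices against each other
      grid <- expand.grid(x = ((seq_len(nx) - 0.5) / nx * p$box[1] + phase) %% p$box[1],
                          y = ((seq_len(nx) - 0.5) / nx * p$box[2] + phase) %% p$box[2])
      sites <- sample.int(nrow(grid), nsp)
      anchors <- cbind(grid$x[sites] + .trunc_jitter(nsp, p$jitter),
                       grid$y[sites] + .trunc_jitter(nsp, p$jitter),
                       planes[[leaf]] + .trunc_jitter(nsp, p$jitter))
      ids <- mol_id + seq_len(nsp)
      mol_id <- mol_id + nsp
      .place_batch(b, .mem_template_for(sp_name), ids, sp_name, anchors, s,
                   if (sp_name == "POPC") "popc" else "membrane_other", .mem_bond)
      ledger[[length(ledger) + 1L]] <- data.frame(
        molecule_id = ids, molecule_name = sp_name, leaflet = leaf,
        stringsAsFactors = FALSE)
    }
  }
  tb <- .builder_tables(b)
  ledger <- do.call(rbind, ledger)
  # self-consistency: ledger labels agree with the z side of the midplane
  first_z <- tb$xyz[match(ledger$molecule_id, tb$atoms$molecule_id), 3]
  stopifnot(all((ledger$leaflet == "upper") == (first_z > mid)))
  list(atoms = tb$atoms, xyz = tb$xyz, chains = tb$chains, ledger = ledger,
       planes = planes, last_id = mol_id)
}

.lnd_species_table <- function(p) {
  il_names <- if (p$il == "ALC-0315") c("ALCP", "ALCD") else c("MC3P", "MC3D")
  tpl_key <- if (p$il == "ALC-0315") "ALC" else "MC3"
  data.frame(
    molecule_name = c(rep(il_names[1], p$n_prot), rep(il_names[2], p$n_deprot),
                      rep("CHOL", p$lnd_composition[["CHOL"]]),
                      rep("DSPC", p$lnd_composition[["DSPC"]])),
    template = c(rep(tpl_key, p$n_prot + p$n_deprot),
                 rep("CHOL", p$lnd_composition[["CHOL"]]),
                 rep("DSPC", p$lnd_composition[["DSPC"]])),
    group = c(rep("protonated", p$n_prot), rep("deprotonated", p$n_deprot),
              rep("other", p$lnd_composition[["CHOL"]] + p$lnd_composition[["DSPC"]])),
    stringsAsFactors = FALSE)
}

.lnd_w_key <- function(template, group) {
  if (template == "DSPC") "dspc"
  else if (group == "protonated") "il_protonated"
  else "il_deprotonated"
}

# compact 3D grid of n anchor points (spacing `sp`), sites nearest the
# centre first (a lattice ball, hence connected at the grid spacing); used
# for the intact droplet and the retained blob
.blob_sites <- function(n, sp, layers_z = NULL) {
  if (n == 0L) return(matrix(numeric(0), 0L, 3L))
  nx <- ceiling(n^(1 / 3)) + 2L
  if (!is.null(layers_z)) nx <- ceiling(sqrt(n / length(layers_z))) + 2L
  g <- expand.grid(x = seq_len(nx), y = seq_len(nx),
                   z = if (is.null(layers_z)) seq_len(ceiling(n^(1 / 3)) + 2L)
                       else seq_along(layers_z))
  g$x <- (g$x - mean(g$x)) * sp
  g$y <- (g$y - mean(g$y)) * sp
  g$z <- if (is.null(layers_z)) (g$z - mean(g$z)) * sp else layers_z[g$z]
  g <- g[order(g$x^2 + g$y^2 + g$z^2), ]
  as.matrix(g[seq_len(n), , drop = FALSE])
}

# droplet in relative coordinates (anchor grid centred at the origin);
# chain beads are NA until .fill_chains
.build_droplet <- function(p, first_id) {
  tab <- .lnd_species_table(p)
  n_mol <- nrow(tab)
  tab <- tab[sample.int(n_mol), , drop = FALSE]   # mix species through the droplet
  anchors <- .blob_sites(n_mol, 0.7)
  anchors[, 1] <- anchors[, 1] + .trunc_jitter(n_mol, 0.015)
  anchors[, 2] <- anchors[, 2] + .trunc_jitter(n_mol, 0.015)
  ids <- first_id - 1L + seq_len(n_mol)
  tab$molecule_id <- ids
  b <- .new_builder()
  for (tk in unique(tab$template)) {
    for (gk in unique(tab$group[tab$template == tk])) {
      sel <- which(tab$template == tk & tab$group == gk)
      .place_batch(b, .lnd_templates[[tk]], ids[sel], tab$molecule_name[sel[1]],
                   anchors[sel, , drop = FALSE], rep(1, length(sel)),
                   .lnd_w_key(tk, gk), .lnd_bond)
    }
  }
  tb <- .builder_tables(b)
  ledger <- data.frame(molecule_id = ids, molecule_name = tab$molecule_name,
                       template = tab$template, group = tab$group,
                       stringsAsFactors = FALSE)
  pick <- function(spec) {
    cand <- switch(spec,
                   IL = which(tab$group %in% c("protonated", "deprotonated")),
                   CHOL = which(tab$molecule_name == "CHOL"),
                   DSPC = which(tab$molecule_name == "DSPC"))
    if (!length(cand)) stop("no molecule of species ", spec, " to plant as deepest",
                            call. = FALSE)
    pr <- cand[tab$group[cand] == "protonated"]
    if (spec == "IL" && length(pr)) pr[1] else cand[1]
  }
  i_deep <- pick(p$deepest_species)
  i_second <- if (!is.null(p$second_species)) {
    j <- pick(p$second_species)
    if (j == i_deep) stop("deepest and second-deepest molecules coincide", call. = FALSE)
    j
  } else NA_integer_
  # plant depth: drop one bead of the designated molecule(s) below the
  # droplet bottom (0.12 nm covers the maximal chain + offset extent)
  zmin0 <- min(tb$xyz[, 3], na.rm = TRUE) - 0.12
  lower_bead <- function(i, depth) {
    rows <- which(tb$atoms$molecule_id == ids[i])
    r <- rows[which.min(tb$xyz[rows, 3])]
    tb$xyz[r, 3] <<- zmin0 - depth
  }
  lower_bead(i_deep, 0.35)
  if (!is.na(i_second)) lower_bead(i_second, 0.18)
  list(atoms = tb$atoms, xyz = tb$xyz, chains = tb$chains, ledger = ledger,
       deepest_id = ids[i_deep],
       second_id = if (is.na(i_second)) NA_integer_ else ids[i_second],
       last_id = ids[n_mol])
}

#' Build a synthetic lipid nanodroplet
#'
#' Packs the LND molecules (ionizable lipids split per the protonation
#' percent, cholesterol, DSPC) on a compact jittered grid forming a single
#' 1.2 nm single-linkage component, with one designated deepest molecule
#' whose lowest bead defines the droplet bottom. The droplet is placed with
#' its lowest bead `gap_nm` above the default upper PO4 sheet position for
#' the parameter box (in a full [generate_fusion_trajectory()] run the
#' same placement is made against the actually built membrane).
#'
#' @param params a [synthetic_params()] object.
#' @return list with `frame` (a [cg_frame]), `ledger` (data.frame
#'   `molecule_id`, `molecule_name`, `group`), `deepest_molecule_id`,
#'   `second_molecule_id` (or `NA`).
#' @examples
#' l <- make_lnd(synthetic_params(seed = 3, protonated_percent = 50, frames = 5))
#' table(l$ledger$molecule_name)
#' @export
make_lnd <- function(params) {
  set.seed(params$seed)
  d <- .build_droplet(params, first_id = 1L)
  xyz <- .fill_chains(d$xyz, d$chains, params$order_w)
  xyz[, 1] <- xyz[, 1] + params$box[1] / 2
  xyz[, 2] <- xyz[, 2] + params$box[2] / 2
  z_target <- params$box[3] / 2 + 2 + params$gap_nm   # upper PO4 plane + gap
  xyz[, 3] <- xyz[, 3] - min(xyz[, 3]) + z_target
  list(frame = cg_frame(d$atoms, xyz, params$box, 0), ledger = d$ledger,
       deepest_molecule_id = d$deepest_id, second_molecule_id = d$second_id)
}

# ---- full trajectory ------------------------------------------------------

#' Generate a synthetic fusion trajectory with planted ground truth
#'
#' Builds the membrane and droplet, then plays a two-phase kinematic script.
#' Before the planted onset the droplet translates rigidly downward so the
#' fusion-depth series `delta_z` decreases linearly from the initial gap to
#' exactly -0.05 nm at the onset frame (an optional shorter negative "blip"
#' can be planted earlier). From the frame after onset the system is in its
#' fused configuration: every ionizable lipid carries a leaflet class drawn
#' once from its species' planted probabilities (head-terminal bead within
#' the 1.2 nm cutoff of its sheet, or in the midplane slab); the retained
#' molecules form one compact connected cluster at the membrane midplane;
#' all other molecules sit on an isolated lattice, pairwise farther apart
#' than the linkage cutoff (isolation is enforced in the xy plane, so it
#' holds whatever class heights the heads take); and tail chains are drawn
#' from the two-population orientation model with the planted aligned
#' weights.
#'
#' @param params a [synthetic_params()] object.
#' @return list of class `synthetic_run` with `trajectory` (a
#'   [cg_trajectory] with origins attached), `topology` (a [cg_topology]
#'   whose `lnd_molecule_ids` mark the droplet) and `ground_truth`
#'   (planted onset frame/time, deepest molecule, expected ionizable-lipid
#'   entry rank, per-molecule classes and retention, class probabilities,
#'   aligned weights, ledgers, seed).
#' @examples
#' run <- generate_fusion_trajectory(synthetic_params(seed = 11, frames = 60,
#'                                                    onset_ps = 4000))
#' run$ground_truth$onset_ps
#' @export
generate_fusion_trajectory <- function(params) {
  p <- params
  set.seed(p$seed)
  mem <- .build_membrane(p)
  drop <- .build_droplet(p, first_id = mem$last_id + 1L)
  atoms <- rbind(mem$atoms, drop$atoms)
  n_mem <- nrow(mem$atoms)
  n_all <- nrow(atoms)
  mem_rows <- seq_len(n_mem)
  lnd_rows <- n_mem + seq_len(nrow(drop$atoms))
  topology <- default_topology(lnd_molecule_ids = drop$ledger$molecule_id)
  atoms$origin <- assign_origins(atoms, topology)

  times <- (seq_len(p$frames) - 1L) * p$spacing_ps
  f_on <- which.min(abs(times - p$onset_ps))
  if (f_on < 2L) stop("planted onset must leave at least one positive frame", call. = FALSE)
  onset_ps <- times[f_on]

  # actual mean height of the upper-leaflet POPC PO4 beads (membrane static)
  po4_upper <- which(mem$atoms$molecule_name == "POPC" & mem$atoms$bead_name == "PO4" &
                       mem$atoms$molecule_id %in%
                         mem$ledger$molecule_id[mem$ledger$leaflet == "upper"])
  h_u <- mean(mem$xyz[po4_upper, 3])

  # phase 1: droplet relative coords (chains drawn once; rigid thereafter)
  drop_rel <- .fill_chains(drop$xyz, drop$chains, p$order_w)
  drop_rel[, 1] <- drop_rel[, 1] + p$box[1] / 2
  drop_rel[, 2] <- drop_rel[, 2] + p$box[2] / 2
  rel_min_z <- min(drop_rel[, 3])
  dz_plan <- p$gap_nm * (1 - times / onset_ps)
  dz_plan[f_on] <- -0.05
  pers_frames <- ceiling(1000 / p$spacing_ps)
  if (!is.null(p$blip)) {
    bf <- max(2L, round(p$blip$at_frac * f_on))
    bl <- bf:min(bf + p$blip$n_frames - 1L, f_on - 1L)
    if (max(bl) >= f_on - pers_frames - 1L) {
      stop("blip too close to the planted onset: the negative runs would merge",
           call. = FALSE)
    }
    dz_plan[bl] <- -p$blip$depth
  }

  # post-fusion layout ------------------------------------------------
  mid <- p$box[3] / 2
  z_class <- c(INNER = mem$planes[["upper"]] - 0.5,
               OUTER = mem$planes[["lower"]] + 0.5,
               MIDPLANE = mid)
  led <- drop$ledger
  draw_classes <- function() {
    cl <- rep(NA_character_, nrow(led))
    for (g in c("protonated", "deprotonated")) {
      gi <- which(led$group == g)
      if (!length(gi)) next
      pr <- p$class_probs[[if (g == "protonated") "IL_PROTONATED" else "IL_DEPROTONATED"]]
      cl[gi] <- sample(c("INNER", "OUTER", "MIDPLANE"), length(gi), replace = TRUE,
                       prob = pr[c("inner", "outer", "midplane")])
    }
    cl
  }
  classes <- draw_classes()
  ret <- logical(nrow(led))
  for (g in c("protonated", "deprotonated", "other")) {
    gi <- which(led$group == g)
    nk <- unname(p$retained[[g]])
    if (nk > 0L) ret[if (length(gi) == 1L) gi else sample(gi, nk)] <- TRUE
  }

  # retained blob at the membrane midplane (compact, connected)
  ctr <- c(p$box[1] / 2, p$box[2] / 2)
  blob <- .blob_sites(sum(ret), 0.55, layers_z = c(0, 0.55, -0.55))
  blob_r <- if (nrow(blob)) max(sqrt(blob[, 1]^2 + blob[, 2]^2)) else 0
  # dispersal lattice: isolation enforced in xy only (every bead of a
  # molecule stays within ~0.13 nm of its anchor xy), so molecules in
  # different cells are > 1.2 nm apart whatever their class heights
  n_cells_x <- floor(p$box[1] / 1.5)
  n_cells_y <- floor(p$box[2] / 1.5)
  cell_xy <- as.matrix(expand.grid(x = (seq_len(n_cells_x) - 0.5) * p$box[1] / n_cells_x,
                                   y = (seq_len(n_cells_y) - 0.5) * p$box[2] / n_cells_y))
  r_excl <- blob_r + 1.55
  far <- sqrt((cell_xy[, 1] - ctr[1])^2 + (cell_xy[, 2] - ctr[2])^2) >= r_excl
  cells <- cell_xy[far, , drop = FALSE]
  disp_il <- !ret & led$group != "other"
  n_disp_other <- sum(!ret & led$group == "other")
  # INNER and OUTER heads sit 3 nm apart in z, so one cell can host one of
  # each and stay beyond the linkage cutoff; midplane heads need their own
  # cell. Per-frame class resampling moves heads between heights, so cells
  # are then exclusive.
  n_mid <- sum(disp_il & classes == "MIDPLANE")
  n_in <- sum(disp_il & classes == "INNER")
  n_out <- sum(disp_il & classes == "OUTER")
  cells_needed <- if (p$class_resample == "per_frame") n_mid + n_in + n_out
                  else n_mid + max(n_in, n_out)
  if (cells_needed > nrow(cells)) {
    stop(sprintf(paste0("dispersal lattice overflow: %d cells needed for %d dispersed ",
                        "ionizable lipids but only %d isolated cells available ",
                        "(enlarge the box or retain more molecules)"),
                 cells_needed, sum(disp_il), nrow(cells)), call. = FALSE)
  }
  cells <- cells[sample.int(nrow(cells)), , drop = FALSE]
  # solvent park for dispersed CHOL/DSPC: same xy cells, stacked well above
  # the membrane; they stay cluster singletons and never enter h_L minima
  park_layers <- seq(mid + 4.4, p$box[3] - 1.2, by = 1.5)
  if (n_disp_other > nrow(cells) * length(park_layers)) {
    stop("dispersal lattice overflow for non-IL molecules", call. = FALSE)
  }

  anchors2 <- matrix(NA_real_, nrow(led), 3L)
  exclusive <- p$class_resample == "per_frame"
  ret_k <- 0L; ci <- 0L; pk <- 0L
  in_k <- 0L; out_k <- 0L   # INNER/OUTER share cells from the back
  for (i in seq_len(nrow(led))) {
    if (ret[i]) {
      ret_k <- ret_k + 1L
      anchors2[i, ] <- c(ctr[1] + blob[ret_k, 1], ctr[2] + blob[ret_k, 2],
                         mid + blob[ret_k, 3])
    } else if (led$group[i] != "other") {
      cell <- if (exclusive || classes[i] == "MIDPLANE") {
        ci <- ci + 1L
        ci
      } else if (classes[i] == "INNER") {
        in_k <- in_k + 1L
        nrow(cells) + 1L - in_k
      } else {
        out_k <- out_k + 1L
        nrow(cells) + 1L - out_k
      }
      anchors2[i, ] <- c(cells[cell, 1], cells[cell, 2], z_class[[classes[i]]])
    } else {
      pk <- pk + 1L
      layer <- ((pk - 1L) %/% nrow(cells)) + 1L
      cell <- ((pk - 1L) %% nrow(cells)) + 1L
      anchors2[i, ] <- c(cells[cell, 1], cells[cell, 2], park_layers[layer])
    }
  }
  anchors2[, 1] <- anchors2[, 1] + .trunc_jitter(nrow(led), 0.015)
  anchors2[, 2] <- anchors2[, 2] + .trunc_jitter(nrow(led), 0.015)

  # fixed beads at the phase-2 anchors; retained ionizable-lipid heads are
  # lifted to their class height at their own xy column
  pos2 <- matrix(NA_real_, nrow(drop$xyz), 3L)
  head_row <- rep(NA_integer_, nrow(led))
  for (i in seq_len(nrow(led))) {
    rows <- which(drop$atoms$molecule_id == led$molecule_id[i])
    tpl <- .lnd_templates[[led$template[i]]]
    fixed <- rows[match(rownames(tpl$beads), drop$atoms$bead_name[rows])]
    pos2[fixed, ] <- sweep(tpl$beads, 2L, anchors2[i, ], "+")
    if (led$group[i] != "other") {
      hb <- head_terminal_bead(topology, led$molecule_name[i])
      head_row[i] <- rows[drop$atoms$bead_name[rows] == hb]
      if (ret[i] && classes[i] != "MIDPLANE") {
        pos2[head_row[i], 3] <- z_class[[classes[i]]]
      }
    }
  }

  # assemble coordinates ----------------------------------------------
  coords <- array(NA_real_, c(n_all, 3L, p$frames))
  static_tails <- p$tail_resample == "static"
  mem_static <- if (static_tails) .fill_chains(mem$xyz, mem$chains, p$order_w)
  pos2_static <- if (static_tails) .fill_chains(pos2, drop$chains, p$order_w)
  il_rows_led <- which(led$group != "other")
  for (f in seq_len(p$frames)) {
    coords[mem_rows, , f] <- if (static_tails) mem_static
                             else .fill_chains(mem$xyz, mem$chains, p$order_w)
    if (f <= f_on) {
      d <- drop_rel
      d[, 3] <- d[, 3] + (h_u + dz_plan[f] - rel_min_z)
      coords[lnd_rows, , f] <- d
    } else {
      pf <- if (static_tails) pos2_static else pos2
      if (p$class_resample == "per_frame") {
        cl_f <- draw_classes()
        for (i in il_rows_led) {
          pf[head_row[i], 3] <- if (ret[i] && cl_f[i] == "MIDPLANE")
            anchors2[i, 3] else z_class[[cl_f[i]]]
        }
      }
      if (!static_tails) pf <- .fill_chains(pf, drop$chains, p$order_w)
      coords[lnd_rows, , f] <- pf
    }
  }

  traj <- cg_trajectory(atoms, coords, times, p$box)
  gt <- list(
    seed = p$seed, onset_ps = onset_ps, onset_frame = f_on,
    deepest_molecule_id = drop$deepest_id,
    deepest_molecule_name = atoms$molecule_name[match(drop$deepest_id, atoms$molecule_id)],
    second_molecule_id = drop$second_id,
    expected_il_rank = if (p$deepest_species == "IL") 1L else
      if (!is.null(p$second_species) && p$second_species == "IL") 2L else NA_integer_,
    classes = data.frame(molecule_id = led$molecule_id,
                         molecule_name = led$molecule_name,
                         group = led$group, class = classes, retained = ret,
                         stringsAsFactors = FALSE),
    class_probs = p$class_probs,
    retained_counts = as.list(p$retained),
    retained_ids = split(led$molecule_id[ret], led$group[ret]),
    order_w = as.list(p$order_w),
    lnd_molecule_ids = led$molecule_id,
    membrane_ledger = mem$ledger,
    h_u = h_u, dz_plan = dz_plan,
    n_beads = n_all
  )
  structure(list(trajectory = traj, topology = topology, ground_truth = gt,
                 params = p),
            class = "synthetic_run")
}

#' @export
print.synthetic_run <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("<synthetic_run> seed %d: %s LND (%d%% protonated) on %s, %d frames\n",
              x$params$seed, x$params$il, x$params$protonated_percent,
              x$params$membrane, n_frames(x$trajectory)))
  cat(sprintf("  planted onset %g ps (frame %d); retained cluster of %d molecules\n",
              gt$onset_ps, gt$onset_frame, sum(gt$classes$retained)))
  invisible(x)
}

#' Write a synthetic run to disk
#'
#' Emits the first frame as GRO, the full trajectory (TRR or the text
#' dialect, by extension), the topology as YAML and the ground truth
#' (including the seed) as JSON.
#'
#' @param run a [generate_fusion_trajectory()] result.
#' @param dir output directory (created if needed).
#' @param traj_format "trr" or "cgtraj".
#' @return invisibly, the named vector of written paths.
#' @export
write_synthetic_run <- function(run, dir, traj_format = c("trr", "cgtraj")) {
  traj_format <- match.arg(traj_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gro = file.path(dir, "system.gro"),
             traj = file.path(dir, paste0("traj.", traj_format)),
             topology = file.path(dir, "topology.yaml"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write_gro(get_frame(run$trajectory, 1L), paths[["gro"]])
  write_trajectory(run$trajectory, paths[["traj"]])
  write_topology(run$topology, paths[["topology"]])
  gt <- run$ground_truth
  gt$dz_plan <- NULL
  jsonlite::write_json(gt, paths[["ground_truth"]], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}
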