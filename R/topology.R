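#' Species classes understood by the pipeline
#'
#' Every residue (molecule) name appearing in a trajectory must be mapped by
#' the topology to one of these classes. The two ionizable-lipid classes are
#' distinguished by residue name because conventional fixed-protonation CG MD
#' assigns the protonation state per molecule for a whole run.
#'
#' @export
SPECIES_CLASSES <- c("IL_PROTONATED", "IL_DEPROTONATED", "PHOSPHOLIPID",
                     "STEROL", "ANIONIC_LIPID", "WATER", "ION")

.origin_levels <- c("LND", "MEMBRANE", "SOLVENT")

.default_origin_for_class <- c(
  IL_PROTONATED   = "LND",
  IL_DEPROTONATED = "LND",
  PHOSPHOLIPID    = "MEMBRANE",
  STEROL          = "MEMBRANE",
  ANIONIC_LIPID   = "MEMBRANE",
  WATER           = "SOLVENT",
  ION             = "SOLVENT"
)

#' Construct a topology specification
#'
#' A topology maps residue (molecule) names to species classes and to the
#' bead roles the analyses need: the head-terminal bead used for leaflet
#' classification (OH for ALC-0315, NC3 for MC3), the bead used for
#' head-group RDFs (NC3 for both ionizable lipids), and the tail segment
#' graph used for P2 order parameters.
#'
#' Species that occur on both sides of the system (cholesterol is part of
#' both the nanodroplet and the endosomal membrane) cannot be assigned an
#' origin from the residue name alone; `lnd_molecule_ids` lists the molecule
#' ids that belong to the nanodroplet and overrides the class default for
#' those molecules. The synthetic generator emits this list in its ground
#' truth; for real trajectories it comes from the system construction.
#'
#' @param molecules data.frame with columns `molecule_name`, `species_class`,
#'   and optionally `head_terminal_bead`, `rdf_bead`, `origin`.
#' @param segments data.frame of tail segment definitions with columns
#'   `molecule_name`, `chain`, `label`, `bead_a`, `bead_b`, `kind`
#'   (`CONSECUTIVE_BOND` or `NONCONSECUTIVE`), or `NULL`.
#' @param lnd_molecule_ids integer molecule ids that belong to the LND.
#' @return object of class `cg_topology`.
#' @export
cg_topology <- function(molecules, segments = NULL, lnd_molecule_ids = integer()) {
  stopifnot(is.data.frame(molecules))
  need <- c("molecule_name", "species_class")
  if (!all(need %in% names(molecules))) {
    stop("topology molecules table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(molecules$species_class), SPECIES_CLASSES)
  if (length(bad)) {
    stop("unknown species_class value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(molecules$molecule_name)) {
    stop("duplicate molecule_name entries in topology", call. = FALSE)
  }
  for (col in c("head_terminal_bead", "rdf_bead", "origin")) {
    if (is.null(molecules[[col]])) molecules[[col]] <- NA_character_
  }
  if (any(!is.na(molecules$origin) & !molecules$origin %in% .origin_levels)) {
    stop("origin overrides must be one of: ", paste(.origin_levels, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(segments)) {
    sneed <- c("molecule_name", "chain", "label", "bead_a", "bead_b", "kind")
    if (!all(sneed %in% names(segments))) {
      stop("topology segments table needs columns: ", paste(sneed, collapse = ", "),
           call. = FALSE)
    }
    if (any(segments$bead_a == segments$bead_b)) {
      stop("segment with bead_a == bead_b in topology", call. = FALSE)
    }
    if (any(!segments$kind %in% c("CONSECUTIVE_BOND", "NONCONSECUTIVE"))) {
      stop("segment kind must be CONSECUTIVE_BOND or NONCONSECUTIVE", call. = FALSE)
    }
  }
  structure(
    list(molecules = molecules, segments = segments,
         lnd_molecule_ids = as.integer(lnd_molecule_ids)),
    class = "cg_topology"
  )
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("<cg_topology>", nrow(x$molecules), "residue name(s):",
      paste(x$molecules$molecule_name, collapse = " "), "\n")
  if (!is.null(x$segments)) {
    cat("  tail segments:", nrow(x$segments), "definitions over",
        length(unique(x$segments$molecule_name)), "species\n")
  }
  if (length(x$lnd_molecule_ids)) {
    cat("  LND molecule ids:", length(x$lnd_molecule_ids), "listed\n")
  }
  invisible(x)
}

.topo_row <- function(topology, molecule_name) {
  i <- match(molecule_name, topology$molecules$molecule_name)
  if (anyNA(i)) {
    stop("residue name(s) not covered by topology: ",
         paste(unique(molecule_name[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  topology$molecules[i, , drop = FALSE]
}

#' Species class for residue names
#' @param topology a [cg_topology].
#' @param molecule_name character vector of residue names.
#' @return character vector of species classes.
#' @export
species_class <- function(topology, molecule_name) {
  .topo_row(topology, molecule_name)$species_class
}

#' Head-terminal bead name for a residue name
#' @inheritParams species_class
#' @export
head_terminal_bead <- function(topology, molecule_name) {
  .topo_row(topology, molecule_name)$head_terminal_bead
}

#' Assign per-bead origins (LND / MEMBRANE / SOLVENT)
#'
#' Origin is assigned once from the topology and is immutable across frames:
#' the class default (ionizable lipids are LND, phospholipids/sterols/anionic
#' lipids MEMBRANE, water/ions SOLVENT) is overridden first by a per-residue
#' `origin` column in the topology, then by membership of the molecule id in
#' `lnd_molecule_ids`.
#'
#' @param atoms data.frame with `molecule_id` and `molecule_name` columns.
#' @param topology a [cg_topology] covering every residue name in `atoms`.
#' @return character vector of origins, one per bead.
#' @export
assign_origins <- function(atoms, topology) {
  rows <- .topo_row(topology, atoms$molecule_name)
  origin <- ifelse(is.na(rows$origin),
                   unname(.default_origin_for_class[rows$species_class]),
                   rows$origin)
  if (length(topology$lnd_molecule_ids)) {
    origin[atoms$molecule_id %in% topology$lnd_molecule_ids] <- "LND"
  }
  origin
}

#' Read a topology specification from a YAML file
#'
#' Layout: a `molecules` map keyed by residue name with fields
#' `species_class`, `head_terminal_bead`, `rdf_bead`, `origin`; an optional
#' `segments` list of `{molecule, chain, label, bead_a, bead_b, kind}`
#' records; an optional `lnd_molecule_ids` integer list.
#'
#' @param path YAML file path.
#' @return a [cg_topology].
#' @export
read_topology <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$molecules)) stop("topology file has no 'molecules' map: ", path, call. = FALSE)
  get_chr <- function(rec, field) {
    v <- rec[[field]]
    if (is.null(v)) NA_character_ else as.character(v)
  }
  mol <- data.frame(
    molecule_name = names(y$molecules),
    species_class = vapply(y$molecules, get_chr, "", field = "species_class"),
    head_terminal_bead = vapply(y$molecules, get_chr, "", field = "head_terminal_bead"),
    rdf_bead = vapply(y$molecules, get_chr, "", field = "rdf_bead"),
    origin = vapply(y$molecules, get_chr, "", field = "origin"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  seg <- NULL
  if (!is.null(y$segments)) {
    seg <- do.call(rbind, lapply(y$segments, function(s) {
      data.frame(molecule_name = s$molecule, chain = s$chain, label = s$label,
                 bead_a = s$bead_a, bead_b = s$bead_b, kind = s$kind,
                 stringsAsFactors = FALSE)
    }))
  }
  cg_topology(mol, seg, as.integer(y$lnd_molecule_ids %||% integer()))
}

#' Write a topology specification to YAML
#' @param topology a [cg_topology].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  mol <- topology$molecules
  mols <- lapply(seq_len(nrow(mol)), function(i) {
    rec <- list(species_class = mol$species_class[i])
    for (f in c("head_terminal_bead", "rdf_bead", "origin")) {
      if (!is.na(mol[[f]][i])) rec[[f]] <- mol[[f]][i]
    }
    rec
  })
  names(mols) <- mol$molecule_name
  out <- list(molecules = mols)
  if (!is.null(topology$segments)) {
    seg <- topology$segments
    out$segments <- lapply(seq_len(nrow(seg)), function(i) {
      list(molecule = seg$molecule_name[i], chain = seg$chain[i], label = seg$label[i],
           bead_a = seg$bead_a[i], bead_b = seg$bead_b[i], kind = seg$kind[i])
    })
  }
  if (length(topology$lnd_molecule_ids)) out$lnd_molecule_ids <- topology$lnd_molecule_ids
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.chain_segments <- function(molecule, chain, beads, noncon = list()) {
  cons <- data.frame(
    molecule_name = molecule, chain = chain,
    label = paste0(beads[-length(beads)], "-", beads[-1]),
    bead_a = beads[-length(beads)], bead_b = beads[-1],
    kind = "CONSECUTIVE_BOND", stringsAsFactors = FALSE
  )
  non <- do.call(rbind, lapply(noncon, function(p) {
    data.frame(molecule_name = molecule, chain = chain,
               label = paste0(p[1], "-", p[2]),
               bead_a = p[1], bead_b = p[2],
               kind = "NONCONSECUTIVE", stringsAsFactors = FALSE)
  }))
  rbind(cons, non)
}

#' Built-in topology for the LND-endosomal membrane systems
#'
#' Covers the residue names used by the synthetic generator and the default
#' Martini-style bead roles: protonated/deprotonated ALC-0315 (`ALCP`/`ALCD`,
#' head-terminal bead OH), protonated/deprotonated MC3 (`MC3P`/`MC3D`,
#' head-terminal bead NC3), DSPC (nanodroplet helper lipid, origin LND),
#' POPC, DOPE, POPS, CHOL, water and ions. Both ionizable lipids use NC3 as
#' the RDF bead. Tail segment definitions follow the two-chain layout of the
#' CG mappings: consecutive glycerol-tail bonds plus non-consecutive
#' first-to-middle and first-to-terminal vectors per chain.
#'
#' @param lnd_molecule_ids molecule ids belonging to the LND (needed to mark
#'   nanodroplet cholesterol as LND-origin).
#' @return a [cg_topology].
#' @export
default_topology <- function(lnd_molecule_ids = integer()) {
  mol <- data.frame(
    molecule_name = c("ALCP", "ALCD", "MC3P", "MC3D", "DSPC",
                      "POPC", "DOPE", "POPS", "CHOL", "W", "NA+", "CL-"),
    species_class = c("IL_PROTONATED", "IL_DEPROTONATED",
                      "IL_PROTONATED", "IL_DEPROTONATED", "PHOSPHOLIPID",
                      "PHOSPHOLIPID", "PHOSPHOLIPID", "ANIONIC_LIPID",
                      "STEROL", "WATER", "ION", "ION"),
    head_terminal_bead = c("OH", "OH", "NC3", "NC3", "NC3",
                           NA, NA, NA, NA, NA, NA, NA),
    rdf_bead = c("NC3", "NC3", "NC3", "NC3", NA, NA, NA, NA, NA, NA, NA, NA),
    origin = c(NA, NA, NA, NA, "LND", NA, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  segs <- rbind(
    .chain_segments("ALCP", "sn1", c("GL1", paste0("T", 1:5)),
                    list(c("T1", "T3"), c("T1", "T5"))),
    .chain_segments("ALCP", "sn2", c("GL2", paste0("T", 6:10)),
                    list(c("T6", "T8"), c("T6", "T10"))),
    .chain_segments("ALCD", "sn1", c("GL1", paste0("T", 1:5)),
                    list(c("T1", "T3"), c("T1", "T5"))),
    .chain_segments("ALCD", "sn2", c("GL2", paste0("T", 6:10)),
                    list(c("T6", "T8"), c("T6", "T10"))),
    .chain_segments("MC3P", "sn1", paste0("CA", 1:5),
                    list(c("CA1", "CA3"), c("CA1", "CA5"))),
    .chain_segments("MC3P", "sn2", paste0("CB", 1:5),
                    list(c("CB1", "CB3"), c("CB1", "CB5"))),
    .chain_segments("MC3D", "sn1", paste0("CA", 1:5),
                    list(c("CA1", "CA3"), c("CA1", "CA5"))),
    .chain_segments("MC3D", "sn2", paste0("CB", 1:5),
                    list(c("CB1", "CB3"), c("CB1", "CB5"))),
    .chain_segments("POPC", "sn1", c("GL1", "C1A", "C2A"), list(c("GL1", "C2A"))),
    .chain_segments("POPC", "sn2", c("GL2", "C1B", "C2B"), list(c("GL2", "C2B")))
  )
  cg_topology(mol, segs, lnd_molecule_ids)
}
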