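# Atomic models: PDB input, hydrogen annotation, membrane slab,
# sequence-derived mass / extinction, and model volume.

#' Construct an atomic model
#'
#' Heavy-atom coordinates with per-atom implicit-hydrogen and labile
#' (exchangeable) hydrogen counts and a transmembrane mask. Crystal
#' structures carry no hydrogens, so hydrogen counts are attached from
#' per-residue templates by [annotate_hydrogens()].
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`,
#'   `resname`, `resno`, `chain`, `atom_name`, `occupancy`.
#' @param implicit_h integer vector, attached hydrogens per atom
#'   (`NA` until annotated).
#' @param labile_h integer vector, exchangeable hydrogens per atom.
#' @param tm_mask logical vector, atom inside the transmembrane slab.
#' @param label free-text label.
#' @return an object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, implicit_h = NULL, labile_h = NULL,
                         tm_mask = NULL, label = "") {
  req <- c("element", "x", "y", "z", "resname", "resno", "chain",
           "atom_name", "occupancy")
  if (!is.data.frame(atoms) || !all(req %in% names(atoms))) {
    stop("atoms must be a data.frame with columns: ",
         paste(req, collapse = ", "))
  }
  n <- nrow(atoms)
  if (n < 1L) stop("empty-selection error: model must contain at least one atom")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  if (is.null(implicit_h)) implicit_h <- rep(NA_integer_, n)
  if (is.null(labile_h)) labile_h <- rep(NA_integer_, n)
  if (is.null(tm_mask)) tm_mask <- rep(FALSE, n)
  stopifnot(length(implicit_h) == n, length(labile_h) == n,
            length(tm_mask) == n)
  ok <- !is.na(implicit_h) & !is.na(labile_h)
  if (any(implicit_h[ok] < labile_h[ok]) || any(labile_h[ok] < 0)) {
    stop("invariant violated: implicit_h >= labile_h >= 0")
  }
  structure(
    list(atoms = atoms, implicit_h = as.integer(implicit_h),
         labile_h = as.integer(labile_h), tm_mask = as.logical(tm_mask),
         label = as.character(label)),
    class = "atomic_model"
  )
}

#' @export
print.atomic_model <- function(x, ...) {
  ann <- if (anyNA(x$implicit_h)) "not annotated" else
    sprintf("%d H (%d labile)", sum(x$implicit_h), sum(x$labile_h))
  cat(sprintf("Atomic model%s: %d atoms, %d chain(s), hydrogens: %s, %d TM atoms\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              nrow(x$atoms), length(unique(x$atoms$chain)), ann,
              sum(x$tm_mask)))
  invisible(x)
}

#' @export
length.atomic_model <- function(x) nrow(x$atoms)

# n x 3 coordinate matrix
#' Coordinates of an atomic model
#' @param model an `atomic_model`.
#' @return numeric matrix with one row per atom and columns x, y, z (Angstrom).
#' @export
coords <- function(model) {
  stopifnot(inherits(model, "atomic_model"))
  m <- as.matrix(model$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

# element from a PDB atom name when the element column is absent/blank
.element_from_name <- function(atom_name) {
  nm <- gsub("[0-9' ]", "", toupper(atom_name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("SE", "FE", "ZN", "MG", "MN"), two, substr(nm, 1, 1))
}

#' Read an atomic model from a PDB file
#'
#' Parses ATOM records via `bio3d`, keeping protein heavy atoms only
#' (waters, hetero-compounds and hydrogens are dropped). Alternate
#' locations are resolved by keeping the highest-occupancy record,
#' ties broken by first appearance.
#'
#' @param path PDB file path.
#' @param assembly_chains optional character vector of chain identifiers
#'   to retain (e.g. `c("A")`); default keeps all chains.
#' @return an un-annotated `atomic_model`.
#' @export
read_structure <- function(path, assembly_chains = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("format error: cannot parse '",
                                           path, "': ", conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  elem <- toupper(trimws(a$elesy))
  blank <- is.na(elem) | !nzchar(elem)
  elem[blank] <- .element_from_name(a$elety[blank])
  keep <- elem != "H" & elem != "D" & !(a$resid %in% c("HOH", "DOD", "WAT"))
  a <- a[keep, , drop = FALSE]
  elem <- elem[keep]
  if (!is.null(assembly_chains)) {
    sel <- a$chain %in% assembly_chains
    a <- a[sel, , drop = FALSE]
    elem <- elem[sel]
  }
  if (nrow(a) == 0L) stop("empty-selection error: no atoms left after filtering")
  occ <- ifelse(is.na(a$o), 1, a$o)
  # alternate locations: keep the highest occupancy, first record on ties
  alt <- ifelse(is.na(a$alt) | a$alt == "", "", a$alt)
  if (any(alt != "")) {
    key <- paste(a$chain, a$resno, a$elety, sep = "|")
    ord <- order(key, -occ, seq_len(nrow(a)))
    dup <- duplicated(key[ord])
    keep2 <- sort(ord[!dup])
    a <- a[keep2, , drop = FALSE]; elem <- elem[keep2]; occ <- occ[keep2]
  }
  atomic_model(
    atoms = data.frame(
      element = elem, x = a$x, y = a$y, z = a$z,
      resname = a$resid, resno = a$resno, chain = a$chain,
      atom_name = trimws(a$elety), occupancy = occ,
      stringsAsFactors = FALSE
    ),
    label = basename(path)
  )
}

#' Write an atomic model (or a list of conformations) to PDB
#'
#' A list of coordinate matrices is written as a multi-MODEL file,
#' which is how transition-pathway frames are exported.
#'
#' @param model an `atomic_model` providing the topology.
#' @param path output path.
#' @param frames optional list of n x 3 coordinate matrices; default is
#'   the model's own coordinates as a single model.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, frames = NULL) {
  stopifnot(inherits(model, "atomic_model"))
  a <- model$atoms
  if (is.null(frames)) frames <- list(coords(model))
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (f in seq_along(frames)) {
    xyz <- frames[[f]]
    stopifnot(nrow(xyz) == nrow(a))
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    nm <- substr(a$atom_name, 1, 4)
    nm <- ifelse(nchar(nm) < 4L, paste0(" ", nm), nm) # short names at col 14
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      (seq_len(nrow(a)) - 1L) %% 99999L + 1L,
      nm, substr(a$resname, 1, 3),
      substr(ifelse(is.na(a$chain), "A", a$chain), 1, 1),
      a$resno %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3],
      a$occupancy, 0, substr(a$element, 1, 2)
    )
    writeLines(lines, con)
    writeLines(if (multi) "ENDMDL" else "END", con)
  }
  if (multi) writeLines("END", con)
  invisible(path)
}

#' Annotate implicit and labile hydrogens
#'
#' Crystal structures lack hydrogens; this attaches per-atom hydrogen
#' counts from per-residue templates at standard (neutral-pH)
#' protonation. The backbone amide nitrogen carries one labile hydrogen
#' (none for proline); side-chain O-H/N-H/S-H hydrogens are labile;
#' carbon-bound hydrogens are not. Chain termini receive one extra
#' labile hydrogen each (N-terminal ammonium, C-terminal carboxyl/OXT).
#'
#' @param model an `atomic_model`.
#' @param protonate optional character vector of residue selectors to
#'   protonate beyond the standard state, each `"<RES><resno>"` (e.g.
#'   `"E35"`, `"H277"` doubly protonates that histidine); one-letter
#'   residue codes refer to Asp/Glu/His. Applied to all chains. This
#'   supports low-pH conditions where a subset of acidic residues is
#'   protonated.
#' @param skip_unknown if `TRUE`, atoms of non-standard residues get
#'   zero hydrogens instead of raising an error.
#' @return the model with `implicit_h` and `labile_h` filled in.
#' @export
annotate_hydrogens <- function(model, protonate = NULL, skip_unknown = FALSE) {
  stopifnot(inherits(model, "atomic_model"))
  a <- model$atoms
  n <- nrow(a)
  imp <- integer(n); lab <- integer(n)
  unknown <- setdiff(unique(a$resname), names(.RESIDUE_H))
  if (length(unknown) && !skip_unknown) {
    stop("annotation error: unknown residue(s): ",
         paste(unknown, collapse = ", "))
  }
  for (i in seq_len(n)) {
    tpl <- .RESIDUE_H[[a$resname[i]]]
    if (is.null(tpl)) next
    ent <- tpl[[a$atom_name[i]]]
    if (is.null(ent)) {
      if (a$atom_name[i] == "OXT") ent <- c(0L, 0L) else next
    }
    imp[i] <- ent[1]; lab[i] <- ent[2]
  }
  # chain termini: +1 labile H on the first backbone N and the last O/OXT
  for (ch in unique(a$chain)) {
    idx <- which(a$chain == ch)
    rfirst <- min(a$resno[idx]); rlast <- max(a$resno[idx])
    i_n <- idx[a$resno[idx] == rfirst & a$atom_name[idx] == "N"]
    if (length(i_n)) {
      imp[i_n[1]] <- imp[i_n[1]] + 1L; lab[i_n[1]] <- lab[i_n[1]] + 1L
    }
    i_o <- idx[a$resno[idx] == rlast & a$atom_name[idx] == "OXT"]
    if (!length(i_o)) idx_o <- idx[a$resno[idx] == rlast & a$atom_name[idx] == "O"]
    else idx_o <- i_o
    if (length(idx_o)) {
      imp[idx_o[1]] <- imp[idx_o[1]] + 1L; lab[idx_o[1]] <- lab[idx_o[1]] + 1L
    }
  }
  # optional extra protonation (low-pH bookkeeping, hydrogen counts only)
  for (sel in protonate) {
    res1 <- toupper(substr(sel, 1, 1))
    resno <- as.integer(substr(sel, 2, nchar(sel)))
    res3 <- names(.AA3TO1)[match(res1, .AA3TO1)]
    if (is.na(res3) || !(res3 %in% names(.PROTONATABLE_ATOM))) {
      stop("cannot protonate selector '", sel,
           "': only Asp (D), Glu (E) and His (H) are supported")
    }
    atom <- .PROTONATABLE_ATOM[[res3]]
    hit <- which(a$resname == res3 & a$resno == resno & a$atom_name == atom)
    if (!length(hit)) {
      warning("protonation selector '", sel, "' matched no atoms")
    }
    imp[hit] <- imp[hit] + 1L; lab[hit] <- lab[hit] + 1L
  }
  atomic_model(a, implicit_h = imp, labile_h = lab, tm_mask = model$tm_mask,
               label = model$label)
}

#' Mark atoms inside a transmembrane slab
#'
#' The membrane is modelled as a z-slab: atoms with `z` in
#' `[z_min, z_max]` are flagged as transmembrane. Labile hydrogens of
#' flagged atoms are shielded from solvent exchange (they stay 1H in
#' D2O) via the transmembrane exchange fraction of [solvent_spec()].
#' The model must be oriented with the membrane normal along z.
#'
#' @param model an `atomic_model`.
#' @param z_min,z_max slab bounds, Angstrom, `z_min < z_max`
#'   (default a 30 A slab centred on z = 0).
#' @return the model with `tm_mask` set.
#' @export
assign_membrane_slab <- function(model, z_min = -15, z_max = 15) {
  stopifnot(inherits(model, "atomic_model"))
  if (!(z_min < z_max)) stop("argument error: z_min must be < z_max")
  z <- model$atoms$z
  model$tm_mask <- z >= z_min & z <= z_max
  model
}

# one-letter sequence per chain from an annotated or raw model
.model_sequences <- function(model) {
  a <- model$atoms
  out <- lapply(unique(a$chain), function(ch) {
    sel <- a$chain == ch & a$atom_name == "CA"
    res1 <- .AA3TO1[a$resname[sel][order(a$resno[sel])]]
    if (anyNA(res1)) stop("unknown residue in chain ", ch)
    paste(res1, collapse = "")
  })
  names(out) <- unique(a$chain)
  unlist(out)
}

#' Sequence mass and 280 nm extinction coefficient
#'
#' Mass is the sum of average residue masses plus one water per chain;
#' the molar extinction coefficient at 280 nm follows the ProtParam
#' convention `5500 nTrp + 1490 nTyr + 125 n(cystine)` (cystines
#' counted as all-paired when `cystines = TRUE`, default reduced).
#'
#' @param x an `atomic_model` or a character vector of one-letter
#'   sequences (one element per chain).
#' @param cystines assume all cysteines form disulfides.
#' @return list with `mass` (g/mol) and `eps280` (M^-1 cm^-1), totals
#'   over all chains.
#' @export
sequence_mass_and_extinction <- function(x, cystines = FALSE) {
  seqs <- if (inherits(x, "atomic_model")) .model_sequences(x) else as.character(x)
  letters1 <- strsplit(toupper(paste(seqs, collapse = "")), "")[[1]]
  bad <- setdiff(letters1, names(.RESIDUE_MASS))
  if (length(bad)) stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  mass <- sum(.RESIDUE_MASS[letters1]) + length(seqs) * .WATER_MASS
  n_trp <- sum(letters1 == "W"); n_tyr <- sum(letters1 == "Y")
  n_cys <- sum(letters1 == "C")
  eps <- 5500 * n_trp + 1490 * n_tyr +
    (if (cystines) 125 * (n_cys %/% 2) else 0)
  list(mass = mass, eps280 = eps)
}

#' Molecular volume of a model
#'
#' Sum of displaced atomic volumes (heavy atoms plus their implicit
#' hydrogens). Dividing by the sequence mass, after unit conversion,
#' gives the partial specific volume used in the I(0) molecular-weight
#' relation.
#'
#' @param model an annotated `atomic_model`.
#' @return volume in Angstrom^3.
#' @export
estimate_molecular_volume <- function(model) {
  stopifnot(inherits(model, "atomic_model"))
  if (anyNA(model$implicit_h)) {
    stop("model must be annotated (annotate_hydrogens) first")
  }
  sum(atom_volume(model$atoms$element)) +
    sum(model$implicit_h) * .ATOM_VOLUME_A3[["H"]]
}

#' Partial specific volume of a model
#'
#' @param model an annotated `atomic_model`.
#' @param mass optional mass in g/mol; defaults to the sequence mass.
#' @return partial specific volume in cm^3/g.
#' @export
partial_specific_volume <- function(model, mass = NULL) {
  v_a3 <- estimate_molecular_volume(model)
  if (is.null(mass)) mass <- sequence_mass_and_extinction(model)$mass
  (v_a3 * 1e-24) * .NA_AVOGADRO / mass
}

#' Solvent and exchange specification
#'
#' Describes the solvent scattering length density and the fraction of
#' labile hydrogens exchanged to deuterium, split between
#' solvent-exposed (soluble) and transmembrane regions. The default
#' mirrors a membrane protein measured in D2O: 90% of labile hydrogens
#' exchanged in the soluble domains, none in the membrane-shielded
#' transmembrane region (those hydrogens remain 1H).
#'
#' @param d2o_fraction D2O volume fraction of the buffer.
#' @param exchanged_fraction_soluble fraction of labile hydrogens
#'   exchanged to D outside the membrane slab.
#' @param exchanged_fraction_tm same, inside the slab.
#' @param rho_solvent optional override of the solvent scattering
#'   length density, cm^-2; computed from `d2o_fraction` by default.
#' @return an object of class `solvent_spec`.
#' @export
solvent_spec <- function(d2o_fraction = 1,
                         exchanged_fraction_soluble = 0.90,
                         exchanged_fraction_tm = 0.0,
                         rho_solvent = NULL) {
  stopifnot(d2o_fraction >= 0, d2o_fraction <= 1,
            exchanged_fraction_soluble >= 0, exchanged_fraction_soluble <= 1,
            exchanged_fraction_tm >= 0, exchanged_fraction_tm <= 1)
  if (is.null(rho_solvent)) rho_solvent <- solvent_sld(d2o_fraction)
  structure(
    list(d2o_fraction = d2o_fraction,
         rho_solvent = rho_solvent,
         exchanged_fraction_soluble = exchanged_fraction_soluble,
         exchanged_fraction_tm = exchanged_fraction_tm),
    class = "solvent_spec"
  )
}

#' @export
print.solvent_spec <- function(x, ...) {
  cat(sprintf(
    "Solvent: %.0f%% D2O, rho = %.3e cm^-2, exchange soluble %.2f / TM %.2f\n",
    100 * x$d2o_fraction, x$rho_solvent,
    x$exchanged_fraction_soluble, x$exchanged_fraction_tm))
  invisible(x)
}
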