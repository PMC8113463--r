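# Atomic data model and coordinate-file I/O.  A structure_model is a flat
# atom table (one row per atom, bio3d-style) plus entry id and provenance;
# residues are identified by (chain, resno, insert).

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")
.dna3 <- c("DA", "DC", "DG", "DT", "DI")
.rna3 <- c("A", "C", "G", "U", "I")

.atom_cols <- c("chain", "resno", "insert", "resid", "kind", "elety",
                "element", "alt", "x", "y", "z", "occ", "b", "hydrogen")

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with columns chain, resno, insert, resid, elety,
#'   x, y, z and optionally element, alt, occ, b.
#' @param entry_id short identifier for the entry.
#' @param provenance list describing where the coordinates came from.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, entry_id = "model", provenance = list()) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty structure: atom table has no rows")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$elety)
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$hydrogen <- toupper(atoms$element) %in% c("H", "D")
  atoms$kind <- classify_residues(atoms)
  atoms <- atoms[, .atom_cols]
  rownames(atoms) <- NULL
  structure(list(entry_id = entry_id, atoms = atoms, provenance = provenance),
            class = "structure_model")
}

# Element symbol from a PDB atom name (fallback when the element column is
# absent): first alphabetic character, except two-letter metals are not
# guessed -- names like "CA " in protein context mean carbon.
guess_element <- function(elety) {
  e <- sub("^[0-9' ]*", "", toupper(trimws(elety)))
  substr(e, 1, 1)
}

# Residue kind (protein / dna / rna / other) per atom, by residue name with
# an O2' fallback separating RNA from DNA for nonstandard names.
classify_residues <- function(atoms) {
  rid <- toupper(trimws(atoms$resid))
  kind <- rep("other", nrow(atoms))
  kind[rid %in% .aa3] <- "protein"
  kind[rid %in% .dna3] <- "dna"
  kind[rid %in% .rna3] <- "rna"
  # fallback: single-letter nucleotide names without O2' are DNA
  amb <- kind == "rna"
  if (any(amb)) {
    key <- residue_key(atoms)
    has_o2p <- tapply(atoms$elety %in% c("O2'", "O2*"), key, any)
    kind[amb & !has_o2p[key][amb]] <- "dna"
  }
  kind
}

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
}

#' Read a coordinate file
#'
#' Reads PDB or mmCIF coordinates into a `structure_model`.  Atoms with zero
#' occupancy are dropped; for alternate locations the highest-occupancy
#' conformer is kept (ties broken by alphabetically first alt-loc id).
#' Hydrogens are retained but flagged, and excluded by default from all
#' downstream geometry.
#'
#' @param path path to the coordinate file.
#' @param format "pdb", "mmcif", or "auto" (by file extension).
#' @return a [structure_model].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "mmcif") suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: no atoms in ", path)
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "", as.character(at$chain)),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    element = if (!is.null(at$elesy)) as.character(at$elesy) else NA_character_,
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE)
  if (any(is.na(atoms$element)) || any(atoms$element %in% c("", "NA")))
    atoms$element <- guess_element(atoms$elety)
  atoms <- atoms[atoms$occ > 0, , drop = FALSE]
  if (nrow(atoms) == 0) stop("empty structure: all atoms have zero occupancy")
  atoms <- resolve_altloc(atoms)
  model <- structure_model(atoms, entry_id = sub("\\.[^.]*$", "", basename(path)),
                           provenance = list(path = path, format = format))
  order_residues(model)
}

# Keep, per (chain, resno, insert, atom name), the highest-occupancy
# conformer; ties go to the alphabetically first alt-loc id.
resolve_altloc <- function(atoms) {
  if (all(atoms$alt == "")) return(atoms)
  key <- paste(residue_key(atoms), atoms$elety, sep = "|")
  ord <- order(key, -atoms$occ, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(key[ord]), , drop = FALSE]
}

# Stable residue ordering within each chain by (resno, insert); chains keep
# first-appearance order.
order_residues <- function(model) {
  at <- model$atoms
  chain_rank <- match(at$chain, unique(at$chain))
  ord <- order(chain_rank, at$resno, at$insert)
  model$atoms <- at[ord, , drop = FALSE]
  rownames(model$atoms) <- NULL
  model
}

#' @export
print.structure_model <- function(x, ...) {
  at <- x$atoms
  key <- residue_key(at)
  cat("<structure_model> ", x$entry_id, ": ",
      length(unique(at$chain)), " chain(s), ",
      length(unique(key)), " residue(s), ",
      nrow(at), " atom(s)\n", sep = "")
  kinds <- tapply(at$kind, at$chain, function(k) names(sort(table(k), decreasing = TRUE))[1])
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, ]
    cat("  chain ", ch, ": ", length(unique(residue_key(sub))), " res (",
        kinds[[ch]], "), resno ", min(sub$resno), "-", max(sub$resno), "\n", sep = "")
  }
  invisible(x)
}

#' Number of atoms in a model
#' @param model a [structure_model].
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Residue summary table
#'
#' One row per residue, in model order.
#'
#' @param model a [structure_model].
#' @return data.frame with chain, resno, insert, resid, kind, n_atoms.
#' @export
residue_table <- function(model) {
  at <- model$atoms
  key <- residue_key(at)
  first <- !duplicated(key)
  out <- at[first, c("chain", "resno", "insert", "resid", "kind")]
  out$n_atoms <- as.integer(table(key)[key[first]])
  rownames(out) <- NULL
  out
}

# Atom table of one residue.
residue_atoms <- function(model, chain, resno, insert = "") {
  at <- model$atoms
  at[at$chain == chain & at$resno == resno & at$insert == insert, , drop = FALSE]
}

#' Apply a rigid motion to a model
#'
#' @param model a [structure_model].
#' @param R 3x3 rotation matrix.
#' @param t translation 3-vector.
#' @return the transformed model.
#' @export
transform_structure <- function(model, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(R)
  model$atoms$x <- xyz[, 1] + t[1]
  model$atoms$y <- xyz[, 2] + t[2]
  model$atoms$z <- xyz[, 3] + t[3]
  model
}

#' Select atoms with a selection expression
#'
#' The selection mini-language combines clauses with `and`:
#' \itemize{
#'   \item `"A"` -- chain A;
#'   \item `"A:5-20"` -- chain A, author residue numbers 5..20 (inclusive);
#'   \item `"A:5-20,30-40"` -- multiple ranges; `"A,B"` -- multiple chains;
#'   \item `"name CA"` or `"name CA,CB"` -- atom-name filter;
#'   \item `"noh"` -- drop hydrogens.
#' }
#' e.g. `"F:94-448 and name CA"`.  Selection preserves atom order and
#' provenance; an empty result is allowed.
#'
#' @param model a [structure_model].
#' @param expression selection string.
#' @return a [structure_model] containing the matching atoms.
#' @export
select_atoms <- function(model, expression) {
  keep <- selection_mask(model, expression)
  out <- model
  out$atoms <- model$atoms[keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out$provenance$selection <- c(model$provenance$selection, expression)
  out
}

selection_mask <- function(model, expression) {
  if (!is.character(expression) || length(expression) != 1 || is.na(expression))
    stop("selection must be a single character string")
  at <- model$atoms
  keep <- rep(TRUE, nrow(at))
  clauses <- strsplit(expression, "\\band\\b")[[1]]
  if (!length(clauses) || !nzchar(trimws(expression)))
    stop("selection syntax error: empty expression")
  pos <- 1
  for (cl in clauses) {
    tok <- trimws(cl)
    if (!nzchar(tok))
      stop("selection syntax error at position ", pos, ": empty clause in '",
           expression, "'")
    if (grepl("^name\\b", tok)) {
      nm <- trimws(strsplit(sub("^name", "", tok), ",")[[1]])
      if (!length(nm) || any(!nzchar(nm)))
        stop("selection syntax error at position ", pos,
             ": 'name' needs atom names in '", expression, "'")
      keep <- keep & at$elety %in% nm
    } else if (tok == "noh") {
      keep <- keep & !at$hydrogen
    } else if (grepl("^[A-Za-z0-9]+(:[-0-9]+(--?[0-9]+)?(,[-0-9]+(--?[0-9]+)?)*)?(,[A-Za-z0-9]+(:.*)?)*$", tok)) {
      keep <- keep & chain_clause_mask(at, tok, expression, pos)
    } else {
      stop("selection syntax error at position ", pos, ": cannot parse '",
           tok, "' in '", expression, "'")
    }
    pos <- pos + nchar(cl) + 3
  }
  keep
}

chain_clause_mask <- function(at, tok, expression, pos) {
  mask <- rep(FALSE, nrow(at))
  # split on commas that start a new chain spec (letter before ':') vs range
  # commas; simplest: split on commas, track current chain.
  parts <- strsplit(tok, ",")[[1]]
  current_chain <- NULL
  for (p in parts) {
    p <- trimws(p)
    if (grepl(":", p)) {
      bits <- strsplit(p, ":", fixed = TRUE)[[1]]
      current_chain <- bits[1]
      rng <- bits[2]
      mask <- mask | (at$chain == current_chain & resno_in_range(at$resno, rng, expression, pos))
    } else if (grepl("^-?[0-9]+(--?[0-9]+)?$", p)) {
      if (is.null(current_chain))
        stop("selection syntax error at position ", pos,
             ": residue range without a chain in '", expression, "'")
      mask <- mask | (at$chain == current_chain & resno_in_range(at$resno, p, expression, pos))
    } else {
      current_chain <- NULL
      mask <- mask | at$chain == p
    }
  }
  mask
}

resno_in_range <- function(resno, rng, expression, pos) {
  m <- regmatches(rng, regexec("^(-?[0-9]+)(?:-(-?[0-9]+))?$", rng))[[1]]
  if (!length(m))
    stop("selection syntax error at position ", pos, ": bad residue range '",
         rng, "' in '", expression, "'")
  lo <- as.integer(m[2])
  hi <- if (nzchar(m[3])) as.integer(m[3]) else lo
  resno >= lo & resno <= hi
}

#' Write a model as a PDB file
#'
#' Standard v3.3 ATOM records with three-decimal coordinates.
#' `read_structure(write_structure(m))` is the identity on the data model
#' within format precision.
#'
#' @param model a [structure_model].
#' @param path output path.
#' @param format only "pdb" is supported.
#' @return the path, invisibly.
#' @export
write_structure <- function(model, path, format = "pdb") {
  if (!identical(format, "pdb")) stop("only PDB output is supported")
  at <- model$atoms
  if (nrow(at) == 0) stop("refusing to write an empty model")
  if (nrow(at) > 99999) stop("PDB capacity exceeded: ", nrow(at), " atoms > 99999")
  if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z)))
    stop("non-finite coordinates")
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = "ATOM",
    resno = at$resno, resid = at$resid, eleno = seq_len(nrow(at)),
    elety = at$elety, chain = ifelse(at$chain == "", " ", at$chain),
    insert = ifelse(at$insert == "", "", at$insert),
    alt = ifelse(at$alt == "", "", at$alt),
    o = at$occ, b = at$b, elesy = at$element)
  invisible(path)
}

# Coordinates of a model (or atom table) as an n x 3 matrix, hydrogens
# optionally excluded.
coords <- function(x, heavy_only = FALSE) {
  at <- if (inherits(x, "structure_model")) x$atoms else x
  if (heavy_only) {
    h <- if (!is.null(at$hydrogen)) at$hydrogen
         else guess_element(at$elety) %in% c("H", "D")
    at <- at[!h, , drop = FALSE]
  }
  as.matrix(at[, c("x", "y", "z")])
}
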