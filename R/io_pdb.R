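#' Read a protein structure from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records (wwPDB v3.3 dialect) into a
#' `structure_model`: a data frame of atoms with chain/residue addressing
#' suitable for the geometry operations in this package. Only the first
#' MODEL block of a multi-model file is read. Alternate locations are
#' resolved by keeping the highest-occupancy altloc (ties broken by file
#' order). HETATM records are retained and flagged in the `het` column.
#' Insertion codes are preserved as part of residue addressing.
#'
#' @param path path to a PDB file.
#' @param id structure identifier; defaults to the file name.
#' @return A `structure_model`: data frame with columns `serial`,
#'   `atom_name`, `resname`, `chain`, `resseq`, `icode`, `x`, `y`, `z`,
#'   `occupancy`, `element`, `het`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines("ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C", pdb)
#' m <- read_pdb(pdb)
#' nrow(m)  # 1
#' @export
read_pdb <- function(path, id = basename(path)) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- grepl("^(ATOM  |HETATM)", paste0(rec, "      "))
  bad <- which(is_atom & nchar(lines) < 54)
  if (length(bad)) {
    stop(sprintf("malformed fixed-width ATOM/HETATM record at line %d of %s",
                 bad[1], path))
  }
  # truncate to first model
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1])]
  src <- path
  if (length(endmdl)) {
    src <- tempfile(fileext = ".pdb")
    writeLines(lines, src)
    on.exit(unlink(src), add = TRUE)
  }
  pdb <- bio3d::read.pdb(src, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty structure: no ATOM/HETATM records in ", path)

  atoms <- data.frame(
    serial    = as.integer(at$eleno),
    atom_name = trimws(at$elety),
    resname   = trimws(at$resid),
    chain     = ifelse(is.na(at$chain), " ", at$chain),
    resseq    = as.integer(at$resno),
    icode     = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    element   = trimws(ifelse(is.na(at$elesy), "", at$elesy)),
    het       = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)
  # element fallback from atom name (first alphabetic character run, H digits stripped)
  noel <- atoms$element == ""
  if (any(noel)) atoms$element[noel] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", atoms$atom_name[noel])

  # altloc resolution: highest occupancy, tie -> first encountered
  alt <- trimws(ifelse(is.na(at$alt), "", at$alt))
  if (any(alt != "")) {
    key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$atom_name, sep = "|")
    keep <- unsplit(lapply(split(seq_len(nrow(atoms)), key), function(ix) {
      if (length(ix) == 1L) return(TRUE)
      best <- ix[which.max(atoms$occupancy[ix])]
      ix == best
    }), key)
    n_in <- nrow(atoms)
    atoms <- atoms[keep, , drop = FALSE]
    hl_log("read_pdb.altloc", n_in, nrow(atoms), "alternate locations collapsed")
  }
  dup <- duplicated(paste(atoms$chain, atoms$resseq, atoms$icode, atoms$atom_name,
                          atoms$het, sep = "|"))
  if (any(dup)) atoms <- atoms[!dup, , drop = FALSE]
  rownames(atoms) <- NULL
  structure_model(atoms, id = id)
}

#' Construct a structure model from an atom table
#'
#' @param atoms data frame with at least `atom_name`, `resname`, `chain`,
#'   `resseq`, `x`, `y`, `z`; missing bookkeeping columns are filled.
#' @param id structure identifier.
#' @export
structure_model <- function(atoms, id = "model") {
  need <- c("atom_name", "resname", "chain", "resseq", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$serial) || anyDuplicated(atoms$serial))
    atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$element))
    atoms$element <- sub("^[0-9]*([A-Za-z]).*$", "\\1", atoms$atom_name)
  if (is.null(atoms$het)) atoms$het <- FALSE
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)), all(is.finite(atoms$z)))
  class(atoms) <- c("structure_model", "data.frame")
  attr(atoms, "id") <- id
  atoms
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- chain_index(x)
  cat(sprintf("structure_model '%s': %d atoms, %d chain(s)\n",
              attr(x, "id") %||% "?", nrow(x), length(ch)))
  for (cn in names(ch))
    cat(sprintf("  chain %s: %d residues\n", cn, length(ch[[cn]])))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chain index of a structure model
#'
#' @param model a `structure_model`.
#' @return named list: chain id -> sorted unique residue keys
#'   (`resseq` with insertion code appended when present).
#' @export
chain_index <- function(model) {
  key <- paste0(model$resseq, ifelse(model$icode == "", "", model$icode))
  lapply(split(key, model$chain), function(k) unique(k))
}

#' Atoms of one residue
#'
#' Returns the atom rows for `(chain, resseq[, icode])`, in file order.
#' @param model a `structure_model`.
#' @param chain single chain identifier.
#' @param resseq author residue number (1-based, preserved from file).
#' @param icode insertion code, default none.
#' @export
residue_atoms <- function(model, chain, resseq, icode = "") {
  model[model$chain == chain & model$resseq == resseq & model$icode == icode, ,
        drop = FALSE]
}

#' Write a structure model as PDB
#'
#' Emits fixed-format ATOM/HETATM records (coordinates to 3 decimals).
#' `write_pdb` followed by [read_pdb()] round-trips atom count, addressing
#' and coordinates at that precision.
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  name4 <- ifelse(nchar(model$atom_name) < 4,
                  sprintf(" %-3s", model$atom_name),
                  sprintf("%-4s", model$atom_name))
  lines <- sprintf("%-6s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(model$het, "HETATM", "ATOM"),
                   model$serial %% 100000L, name4, model$resname,
                   model$chain, model$resseq,
                   ifelse(model$icode == "", " ", model$icode),
                   model$x, model$y, model$z, model$occupancy, 0,
                   model$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
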