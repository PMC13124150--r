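#' Structural models
#'
#' A `structure_model` is a flat atom table: one row per atom with chain,
#' residue number and name, atom name, element, Cartesian coordinates in
#' Angstrom, and a heteroatom flag. Atom records with alternate locations
#' are resolved to the highest-occupancy conformer at parse time.
#'
#' @name structure_model
NULL

new_structure_model <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resid", "resname", "atom", "element",
            "x", "y", "z", "het")
  missing <- setdiff(need, names(atoms))
  if (length(missing)) {
    acd_error(paste("atom table lacks columns:",
                    paste(missing, collapse = ", ")), "format_error")
  }
  if (nrow(atoms) == 0L) acd_error("no atoms", "format_error")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    acd_error("non-finite coordinates", "format_error")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<structure_model> %d atoms, %d chains (%s), %d residues\n",
              nrow(a), length(unique(a$chain)),
              paste(unique(a$chain), collapse = ","),
              nrow(unique(a[, c("chain", "resid")]))))
  invisible(x)
}

#' Load a structural model from PDB or mmCIF
#'
#' The format is chosen by extension (`.cif`/`.mmcif` vs anything else =
#' PDB). Both parsers keep heteroatoms and waters, flagged in the `het`
#' column, and resolve alternate locations to the highest occupancy.
#'
#' @param path Path to a PDB or mmCIF file.
#' @return A `structure_model`.
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) {
    acd_error(sprintf("file not found: %s", path), "format_error")
  }
  if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) {
    parse_mmcif(path)
  } else {
    parse_pdb(path)
  }
}

parse_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | rec == "HETATM"
  # only the first model of a multi-model file
  endmdl <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(endmdl)) keep <- keep & seq_along(lines) < endmdl[1]
  lines <- lines[keep]
  if (length(lines) == 0L) {
    acd_error(sprintf("no ATOM records in %s", path), "format_error")
  }
  f <- function(a, b) trimws(substr(lines, a, b))
  num <- function(a, b) suppressWarnings(as.numeric(substr(lines, a, b)))
  atoms <- data.frame(
    chain = f(22, 22), resid = as.integer(num(23, 26)),
    resname = f(18, 20), atom = f(13, 16),
    element = f(77, 78), altloc = f(17, 17), occ = num(55, 60),
    x = num(31, 38), y = num(39, 46), z = num(47, 54),
    het = substr(lines, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z) |
          is.na(atoms$resid))) {
    acd_error(sprintf("malformed ATOM records in %s", path), "format_error")
  }
  atoms$element[atoms$element == ""] <-
    substr(gsub("[0-9]", "", atoms$atom[atoms$element == ""]), 1, 1)
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms <- resolve_altloc(atoms)
  new_structure_model(atoms[, c("chain", "resid", "resname", "atom",
                                "element", "x", "y", "z", "het")])
}

# Keep, per (chain, resid, atom), the highest-occupancy alternate location.
resolve_altloc <- function(atoms) {
  if (all(atoms$altloc == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resid, atoms$atom, sep = "|")
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, ]
  atoms[!duplicated(paste(atoms$chain, atoms$resid, atoms$atom, sep = "|")), ]
}

parse_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # locate the atom_site loop
  loop_starts <- which(trimws(lines) == "loop_")
  atoms <- NULL
  for (ls in loop_starts) {
    i <- ls + 1L
    fields <- character()
    while (i <= length(lines) && grepl("^_atom_site\\.", trimws(lines[i]))) {
      fields <- c(fields, sub("^_atom_site\\.", "", trimws(lines[i])))
      i <- i + 1L
    }
    if (length(fields) == 0L) next
    rows <- character()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || grepl("^(#|loop_|_)", ln)) break
      rows <- c(rows, ln)
      i <- i + 1L
    }
    tab <- utils::read.table(text = rows, header = FALSE,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    if (ncol(tab) != length(fields)) {
      acd_error(sprintf("atom_site loop malformed in %s", path),
                "format_error")
    }
    names(tab) <- fields
    atoms <- tab
    break
  }
  if (is.null(atoms)) {
    acd_error(sprintf("no atom_site loop in %s", path), "format_error")
  }
  get <- function(nm, alt = NULL, default = NA_character_) {
    if (nm %in% names(atoms)) return(atoms[[nm]])
    if (!is.null(alt) && alt %in% names(atoms)) return(atoms[[alt]])
    rep(default, nrow(atoms))
  }
  out <- data.frame(
    chain = get("auth_asym_id", "label_asym_id"),
    resid = as.integer(get("auth_seq_id", "label_seq_id")),
    resname = get("auth_comp_id", "label_comp_id"),
    atom = gsub('"', "", get("auth_atom_id", "label_atom_id")),
    element = get("type_symbol", default = ""),
    altloc = get("label_alt_id", default = "."),
    occ = suppressWarnings(as.numeric(get("occupancy", default = "1"))),
    x = suppressWarnings(as.numeric(get("Cartn_x"))),
    y = suppressWarnings(as.numeric(get("Cartn_y"))),
    z = suppressWarnings(as.numeric(get("Cartn_z"))),
    het = get("group_PDB", default = "ATOM") == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$x) | is.na(out$y) | is.na(out$z))) {
    acd_error(sprintf("malformed coordinates in %s", path), "format_error")
  }
  out$altloc[out$altloc %in% c(".", "?")] <- ""
  out$occ[is.na(out$occ)] <- 1
  out <- resolve_altloc(out)
  new_structure_model(out[, c("chain", "resid", "resname", "atom",
                              "element", "x", "y", "z", "het")])
}

#' Write a structure model (or label ensembles) as PDB
#'
#' A minimal fixed-column PDB writer, sufficient for round-tripping models
#' produced by the synthetic generator and for exporting rotamer ensembles
#' (one MODEL per rotamer) for visual inspection.
#'
#' @param model A `structure_model`, or a list of [label_ensemble] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(model, "structure_model")) {
    writeLines(format_pdb_atoms(model$atoms), con)
    writeLines("END", con)
  } else if (is.list(model) &&
             all(vapply(model, inherits, logical(1), "label_ensemble"))) {
    nmod <- max(vapply(model, function(e) nrow(e$points), integer(1)))
    for (m in seq_len(nmod)) {
      writeLines(sprintf("MODEL     %4d", m), con)
      serial <- 0L
      for (e in model) {
        if (m > nrow(e$points)) next
        serial <- serial + 1L
        writeLines(sprintf(
          "HETATM%5d  X   %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, substr(e$label_type, 1, 3), e$site$chain, e$site$resid,
          e$points[m, 1], e$points[m, 2], e$points[m, 3], 1, e$weights[m]),
          con)
      }
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    acd_error("cannot write this object as PDB", "format_error")
  }
  invisible(path)
}

format_pdb_atoms <- function(a) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)),
          ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom), "",
          a$resname, a$chain, a$resid, a$x, a$y, a$z, 1, 0,
          toupper(a$element))
}

#' Enumerate native FRET donors (Trp and Tyr residues)
#'
#' @param model A `structure_model`.
#' @return A data.frame with one row per TRP/TYR residue: `chain`, `resid`,
#'   `resname`. Attribute `"per_chain"` holds a count table.
#' @export
find_native_donors <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  res <- unique(a[!a$het & a$resname %in% c("TRP", "TYR"),
                  c("chain", "resid", "resname")])
  res <- res[order(res$chain, res$resid), ]
  rownames(res) <- NULL
  attr(res, "per_chain") <- if (nrow(res)) table(res$chain, res$resname)
                            else table(character(), character())
  res
}

# Residue atom subset; errors if absent.
site_atoms <- function(model, chain, resid) {
  a <- model$atoms
  sub <- a[a$chain == chain & a$resid == resid, ]
  if (nrow(sub) == 0L) {
    acd_error(sprintf("no residue %s/%d in model", chain, resid),
              "site_error")
  }
  sub
}
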