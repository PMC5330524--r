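ELEMENTS <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne")

#' Molecular geometry container
#'
#' A closed-shell molecule: atomic numbers, Cartesian coordinates in bohr,
#' net charge and (singlet) spin multiplicity.  Only even electron counts are
#' accepted because every electronic-structure stage in this package is
#' restricted (closed-shell).
#'
#' @param Z integer vector of atomic numbers.
#' @param xyz numeric matrix, one row per atom, columns x, y, z in bohr.
#' @param charge net molecular charge (electrons).
#' @param comment free-text provenance string carried through file output.
#' @return An object of class `xcw_molecule`.
#' @export
molecule <- function(Z, xyz, charge = 0L, comment = "") {
  Z <- as.integer(Z)
  xyz <- matrix(as.numeric(xyz), nrow = length(Z), ncol = 3)
  nelec <- sum(Z) - charge
  if (nelec <= 0) stop("molecule has no electrons")
  if (nelec %% 2 != 0) {
    stop("open-shell systems are not supported: electron count ", nelec, " is odd")
  }
  structure(
    list(Z = Z, xyz = xyz, charge = as.integer(charge),
         multiplicity = 1L, nelec = as.integer(nelec), comment = comment),
    class = "xcw_molecule")
}

#' @export
print.xcw_molecule <- function(x, ...) {
  cat(sprintf("<molecule: %d atoms, %d electrons, charge %+d>\n",
              length(x$Z), x$nelec, x$charge))
  sym <- element_symbol(x$Z)
  for (i in seq_along(x$Z)) {
    cat(sprintf("  %-2s %12.7f %12.7f %12.7f  (bohr)\n", sym[i],
                x$xyz[i, 1], x$xyz[i, 2], x$xyz[i, 3]))
  }
  invisible(x)
}

element_symbol <- function(Z) ELEMENTS[Z]

element_number <- function(sym) {
  idx <- match(sym, ELEMENTS)
  if (anyNA(idx)) stop("unknown element symbol: ", paste(sym[is.na(idx)], collapse = ", "))
  idx
}

#' Nuclear repulsion energy
#' @param mol an `xcw_molecule`.
#' @return Energy in hartree.
#' @export
nuclear_repulsion <- function(mol) {
  e <- 0
  n <- length(mol$Z)
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- sqrt(sum((mol$xyz[i, ] - mol$xyz[j, ])^2))
      e <- e + mol$Z[i] * mol$Z[j] / r
    }
  }
  e
}

#' Read / write XYZ geometry files
#'
#' Standard XYZ: atom count, comment line, then `symbol x y z` in angstrom.
#' Coordinates are converted to bohr on input.
#'
#' @param path file path.
#' @param charge net charge to attach (XYZ does not carry one).
#' @return `read_xyz`: an `xcw_molecule`.
#' @export
read_xyz <- function(path, charge = 0L) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ: first line must be the atom count")
  comment <- if (length(lines) >= 2) lines[2] else ""
  rows <- lines[3:(2 + n)]
  parts <- strsplit(trimws(rows), "\\s+")
  sym <- vapply(parts, `[[`, "", 1L)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  molecule(element_number(sym), angstrom_to_bohr(xyz), charge = charge, comment = comment)
}

#' @rdname read_xyz
#' @param mol an `xcw_molecule` to write.
#' @export
write_xyz <- function(mol, path) {
  sym <- element_symbol(mol$Z)
  xyz <- bohr_to_angstrom(mol$xyz)
  lines <- c(as.character(length(mol$Z)), mol$comment,
             sprintf("%-2s %16.10f %16.10f %16.10f", sym, xyz[, 1], xyz[, 2], xyz[, 3]))
  writeLines(lines, path)
  invisible(path)
}
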