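# Gaussian basis sets: plain-text tables shipped with the package, parsed
# into per-atom shell lists and instantiated on a molecule as Cartesian
# contracted shells.  Contraction coefficients in the tables refer to
# normalized primitives; on instantiation each primitive coefficient absorbs
# its (l,0,0) normalization constant and the contraction is renormalized.
# Cartesian shells share the radial normalization of the (l,0,0) component
# (the common "6d" convention); this is a diagonal AO scaling and leaves the
# variational space, energies and densities unchanged.

#' List or parse basis-set tables
#'
#' Basis sets ship as plain-text tables under `inst/extdata/basis`.  The
#' format is `ATOM <symbol>` followed by shell blocks `S|P|D|SP <nprim>` with
#' one `exponent coefficient` (or `exponent s-coef p-coef` for SP) row per
#' primitive.
#'
#' @param name basis-set name (file name without extension), or a path to a
#'   basis file.
#' @return A named list mapping element symbols to shell descriptors.
#' @export
load_basis_table <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "basis", paste0(tolower(name), ".txt"), package = "xcwfit")
  if (!nzchar(path) || !file.exists(path)) stop("unknown basis set: ", name)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tab <- list()
  i <- 1
  cur <- NULL
  while (i <= length(lines)) {
    parts <- strsplit(lines[i], "\\s+")[[1]]
    if (parts[1] == "ATOM") {
      cur <- parts[2]
      tab[[cur]] <- list()
      i <- i + 1
    } else {
      type <- parts[1]
      np <- as.integer(parts[2])
      rows <- lines[(i + 1):(i + np)]
      m <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
      if (type == "SP") {
        tab[[cur]] <- c(tab[[cur]],
                        list(list(l = 0L, exps = m[, 1], coefs = m[, 2]),
                             list(l = 1L, exps = m[, 1], coefs = m[, 3])))
      } else {
        l <- match(type, c("S", "P", "D", "F")) - 1L
        if (is.na(l)) stop("unknown shell type: ", type)
        tab[[cur]] <- c(tab[[cur]], list(list(l = l, exps = m[, 1], coefs = m[, 2])))
      }
      i <- i + np + 1
    }
  }
  tab
}

# overlap of two normalized (l,0,0) primitives with exponents a, b on one center
prim_pair_overlap <- function(a, b, l) (2 * sqrt(a * b) / (a + b))^(l + 1.5)

#' Instantiate a basis set on a molecule
#'
#' @param mol an [molecule()].
#' @param name basis-set name (e.g. `"sto-3g"`, `"6-31g"`, `"6-31gdp"`).
#' @return An object of class `xcw_basis`: the shell list (with normalized,
#'   renormalized contraction coefficients and centers in bohr), the AO count
#'   and bookkeeping metadata.
#' @export
build_basis <- function(mol, name) {
  if (inherits(mol, "xcw_basis")) return(mol)
  if (inherits(name, "xcw_basis")) return(name)
  tab <- load_basis_table(name)
  sym <- element_symbol(mol$Z)
  shells <- list()
  for (i in seq_along(mol$Z)) {
    at <- tab[[sym[i]]]
    if (is.null(at)) stop("basis ", name, " has no entry for element ", sym[i])
    for (sh in at) {
      coefs <- sh$coefs * vapply(sh$exps, cpp_prim_norm, 0, i = sh$l, j = 0L, k = 0L)
      # renormalize the contracted function
      nrm <- 0
      for (p in seq_along(sh$exps)) {
        for (q in seq_along(sh$exps)) {
          nrm <- nrm + sh$coefs[p] * sh$coefs[q] *
            prim_pair_overlap(sh$exps[p], sh$exps[q], sh$l)
        }
      }
      coefs <- coefs / sqrt(nrm)
      shells[[length(shells) + 1]] <- list(
        l = as.integer(sh$l), center = as.numeric(mol$xyz[i, ]),
        exps = as.numeric(sh$exps), coefs = coefs, atom = i)
    }
  }
  nbf <- sum(vapply(shells, function(s) (s$l + 1) * (s$l + 2) / 2, 0))
  structure(list(shells = shells, nbf = as.integer(nbf), name = name,
                 molecule = mol),
            class = "xcw_basis")
}

#' @export
print.xcw_basis <- function(x, ...) {
  cat(sprintf("<basis %s: %d shells, %d Cartesian AOs on %d atoms>\n",
              x$name, length(x$shells), x$nbf, length(x$molecule$Z)))
  invisible(x)
}

#' One- and two-electron integrals over a basis
#'
#' Computes overlap, kinetic, nuclear-attraction matrices and the full
#' two-electron repulsion tensor for a molecule/basis pair.  All downstream
#' stages (SCF, CI, constrained SCF) consume this context object.
#'
#' @param mol an [molecule()].
#' @param basis basis-set name or an `xcw_basis`.
#' @return A list of class `xcw_ints` with elements `S`, `T`, `V`, `h`
#'   (= T + V), `eri` (nbf^4 array, chemist notation), `X` (symmetric
#'   orthogonalizer S^-1/2), `enuc`, `basis`, `molecule`.
#' @export
compute_integrals <- function(mol, basis) {
  bs <- build_basis(mol, basis)
  mol <- bs$molecule
  st <- cpp_overlap_kinetic(bs$shells)
  V <- cpp_nuclear(bs$shells, as.numeric(mol$Z), mol$xyz)
  eri <- cpp_eri(bs$shells)
  S <- st$S
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-9) {
    stop("AO overlap matrix is numerically singular (min eigenvalue ",
         format(min(es$values)), ")")
  }
  X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  structure(list(S = S, T = st$T, V = V, h = st$T + V, eri = eri, X = X,
                 enuc = nuclear_repulsion(mol), nbf = bs$nbf,
                 basis = bs, molecule = mol),
            class = "xcw_ints")
}
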