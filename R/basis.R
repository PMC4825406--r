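#' Contracted Cartesian Gaussian shells and basis sets
#'
#' A shell is a contracted Cartesian Gaussian: a centre atom, an angular
#' momentum (0 = s, 1 = p, 2 = d; d shells carry the 6 Cartesian components
#' in the order xx, xy, xz, yy, yz, zz), and matched vectors of primitive
#' exponents (bohr^-2) and contraction coefficients. Primitives are
#' normalized at construction; the contracted function is normalized per
#' Cartesian component so that the overlap diagonal is exactly 1.
#'
#' @param center_atom 1-based index of the centre atom in the geometry.
#' @param angular_momentum integer 0, 1, or 2.
#' @param exponents positive primitive exponents (bohr^-2).
#' @param contraction_coeffs contraction coefficients, same length.
#' @return an object of class \code{qmmd_shell}.
#' @export
gaussian_shell <- function(center_atom, angular_momentum, exponents,
                           contraction_coeffs) {
  l <- as.integer(angular_momentum)
  if (l < 0L || l > 2L) stop("angular momentum must be 0, 1 or 2 (s, p, d)")
  if (length(exponents) != length(contraction_coeffs)) {
    stop("exponents and contraction coefficients must have equal length")
  }
  if (any(exponents <= 0)) stop("primitive exponents must be positive")
  # primitive normalization for the axial component (l,0,0)
  dfact <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))
  nrm <- (2 * exponents / pi)^0.75 * (4 * exponents)^(l / 2) /
    sqrt(dfact(2 * l - 1))
  structure(list(center_atom = as.integer(center_atom),
                 angular_momentum = l,
                 exponents = as.numeric(exponents),
                 contraction_coeffs = as.numeric(contraction_coeffs) * nrm),
            class = "qmmd_shell")
}

.cart_components <- function(l) {
  out <- list()
  for (lx in seq(l, 0)) for (ly in seq(l - lx, 0)) {
    out[[length(out) + 1L]] <- c(lx, ly, l - lx - ly)
  }
  out
}

#' Assemble a basis set from shells
#'
#' Computes the Cartesian basis dimension, the per-function normalization
#' vector and the flattened arrays consumed by the integral kernels.
#'
#' @param shells list of \code{qmmd_shell} objects.
#' @param geom the \code{qmmd_geometry} the shells refer to.
#' @return an object of class \code{qmmd_basis} with \code{shells},
#'   \code{n_basis}, \code{norm} (per-function contracted normalization) and
#'   internal flattened shell arrays.
#' @export
basis_set <- function(shells, geom) {
  if (length(shells) == 0L) stop("no basis functions")
  centers <- vapply(shells, `[[`, integer(1), "center_atom")
  if (any(centers < 1L) || any(centers > n_atoms(geom))) {
    stop("shell centre index outside geometry")
  }
  dfact <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))
  norm <- numeric(0)
  labels <- character(0)
  for (sh in shells) {
    l <- sh$angular_momentum
    comps <- .cart_components(l)
    a <- sh$exponents; c0 <- sh$contraction_coeffs
    psum <- outer(a, a, `+`)
    cc <- outer(c0, c0)
    for (comp in comps) {
      self <- sum(cc * (pi / psum)^1.5 / (2 * psum)^l) *
        dfact(2 * comp[1] - 1) * dfact(2 * comp[2] - 1) *
        dfact(2 * comp[3] - 1)
      norm <- c(norm, 1 / sqrt(self))
      labels <- c(labels, paste0(c("s", "p", "d")[l + 1],
                                 paste(rep(c("x", "y", "z"), comp),
                                       collapse = "")))
    }
  }
  flat <- list(
    centers = centers,
    sl = vapply(shells, `[[`, integer(1), "angular_momentum"),
    nprim = vapply(shells, function(s) length(s$exponents), integer(1)),
    exps = unlist(lapply(shells, `[[`, "exponents")),
    coefs = unlist(lapply(shells, `[[`, "contraction_coeffs"))
  )
  structure(list(shells = shells, n_basis = length(norm), norm = norm,
                 labels = labels, flat = flat),
            class = "qmmd_basis")
}

#' @export
print.qmmd_basis <- function(x, ...) {
  cat(sprintf("<qmmd_basis: %d shells, %d Cartesian functions>\n",
              length(x$shells), x$n_basis))
  invisible(x)
}

#' Parse a plain-text basis definition file
#'
#' Format: blocks starting with \code{element <symbol>}, followed by shell
#' blocks: a line with the shell letter (\code{S}, \code{P}, \code{D} or the
#' combined \code{SP}) and then one row per primitive with the exponent and
#' the contraction coefficient(s) (two coefficient columns for \code{SP}).
#' Lines starting with \code{#} and blank lines are ignored.
#'
#' @param path path to the basis file.
#' @return named list mapping element symbol to a list of shell templates
#'   (each: \code{l}, \code{exponents}, \code{coeffs}).
#' @export
read_basis_file <- function(path) {
  if (!file.exists(path)) stop("basis file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lib <- list()
  cur_el <- NULL
  i <- 1L
  lmap <- c(S = 0L, P = 1L, D = 2L)
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^element\\s+", ln, ignore.case = TRUE)) {
      cur_el <- sub("^element\\s+", "", ln, ignore.case = TRUE)
      lib[[cur_el]] <- list()
      i <- i + 1L
    } else if (toupper(ln) %in% c("S", "P", "D", "SP")) {
      if (is.null(cur_el)) stop("shell block before any element in ", path)
      kind <- toupper(ln)
      i <- i + 1L
      rows <- list()
      while (i <= length(lines) &&
             grepl("^[-+0-9.]", lines[i])) {
        rows[[length(rows) + 1L]] <- as.numeric(strsplit(lines[i],
                                                         "\\s+")[[1]])
        i <- i + 1L
      }
      if (length(rows) == 0L) stop("empty shell block in ", path)
      m <- do.call(rbind, rows)
      if (kind == "SP") {
        if (ncol(m) != 3L) stop("SP block needs 3 columns in ", path)
        lib[[cur_el]] <- c(lib[[cur_el]],
                           list(list(l = 0L, exponents = m[, 1],
                                     coeffs = m[, 2]),
                                list(l = 1L, exponents = m[, 1],
                                     coeffs = m[, 3])))
      } else {
        if (ncol(m) != 2L) stop(kind, " block needs 2 columns in ", path)
        lib[[cur_el]] <- c(lib[[cur_el]],
                           list(list(l = lmap[[kind]], exponents = m[, 1],
                                     coeffs = m[, 2])))
      }
    } else {
      stop("cannot parse basis file line: '", ln, "'")
    }
  }
  lib
}

#' Build a basis set for a geometry from a basis library or file
#'
#' @param geom a \code{qmmd_geometry}.
#' @param basis either a path to a basis text file, the name of a shipped
#'   fixture basis (\code{"toy-minimal"} or \code{"toy-dz"}), or a library
#'   list as returned by \code{\link{read_basis_file}}.
#' @return a \code{qmmd_basis}.
#' @export
load_basis <- function(geom, basis) {
  if (is.character(basis)) {
    if (basis %in% c("toy-minimal", "toy-dz")) {
      basis <- system.file("extdata", paste0(basis, ".bas"),
                           package = "qmmd", mustWork = TRUE)
    }
    basis <- read_basis_file(basis)
  }
  shells <- list()
  for (a in seq_len(n_atoms(geom))) {
    el <- geom$elements[a]
    tmpl <- basis[[el]]
    if (is.null(tmpl)) stop("no basis entry for element ", el)
    for (t in tmpl) {
      shells[[length(shells) + 1L]] <-
        gaussian_shell(a, t$l, t$exponents, t$coeffs)
    }
  }
  basis_set(shells, geom)
}
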