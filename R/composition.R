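#' Elemental compositions
#'
#' An elemental composition is a named integer vector mapping element (or
#' fixed-isotope pseudo-element) tokens to non-negative counts, with class
#' \code{"elem_comp"}. It is the basis for all monoisotopic-mass and
#' isotope-pattern arithmetic in the package.
#'
#' @param ... Element counts, e.g. \code{composition(C = 8, H = 9, N = 2, O = 3)}.
#' @return An \code{elem_comp} object.
#' @examples
#' composition(H = 2, O = 1)
#' parse_formula("C8H9N2O3")
#' @export
composition <- function(...) {
  x <- c(...)
  if (length(x) == 0) x <- integer(0)
  as_composition(x)
}

#' @param x A named numeric vector of counts.
#' @rdname composition
#' @export
as_composition <- function(x) {
  if (inherits(x, "elem_comp")) return(x)
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
    stop("composition counts must be named by element token")
  bad <- setdiff(names(x), names(.nq_catalog))
  if (length(bad))
    stop("unknown element token(s): ", paste(bad, collapse = ", "))
  if (any(x < 0) || any(x != round(x)))
    stop("composition counts must be non-negative integers")
  x <- x[x > 0]
  out <- structure(as.integer(x), names = names(x), class = "elem_comp")
  # canonical token order keeps comparisons and printing stable
  out[order(match(names(out), names(.nq_catalog)))]
}

#' @export
print.elem_comp <- function(x, ...) {
  if (!length(x)) cat("<empty composition>\n")
  else cat(paste0(names(x), unclass(x), collapse = " "), "\n")
  invisible(x)
}

#' @export
`[.elem_comp` <- function(x, i) {
  structure(NextMethod(), class = "elem_comp")
}

#' Element-wise composition arithmetic
#'
#' Addition and subtraction of compositions; subtraction that would drive
#' any count negative is an error (removing atoms a molecule does not
#' have).
#'
#' @param a,b \code{elem_comp} objects (or named count vectors).
#' @return An \code{elem_comp}.
#' @export
comp_add <- function(a, b) {
  a <- as_composition(a); b <- as_composition(b)
  toks <- union(names(a), names(b))
  out <- vapply(toks, function(t) {
    sum(a[names(a) == t]) + sum(b[names(b) == t])
  }, numeric(1))
  as_composition(out)
}

#' @rdname comp_add
#' @export
comp_subtract <- function(a, b) {
  a <- as_composition(a); b <- as_composition(b)
  toks <- union(names(a), names(b))
  out <- vapply(toks, function(t) {
    sum(a[names(a) == t]) - sum(b[names(b) == t])
  }, numeric(1))
  if (any(out < 0))
    stop("composition subtraction yields negative count for: ",
         paste(toks[out < 0], collapse = ", "))
  as_composition(out)
}

#' Parse a molecular formula string
#'
#' Accepts Hill-style formulas such as \code{"C8H9N2O3"} or
#' \code{"C62H88N18O16"}. Fixed-isotope tokens use their catalog names
#' directly (e.g. \code{"N15"} written as \code{"[N15]2"} or a named count
#' via [composition()]).
#'
#' @param formula Formula string.
#' @return An \code{elem_comp}.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  s <- gsub("\\s", "", formula)
  pat <- "\\[([A-Za-z0-9]+)\\]([0-9]*)|([A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pat, s, perl = TRUE)
  if (m[[1]][1] == -1 || sum(attr(m[[1]], "match.length")) != nchar(s))
    stop("cannot parse formula: ", formula)
  parts <- regmatches(s, m)[[1]]
  counts <- integer(0)
  for (p in parts) {
    g <- regmatches(p, regexec(pat, p, perl = TRUE))[[1]]
    tok <- if (nzchar(g[2])) g[2] else g[4]
    n <- if (nzchar(g[2])) g[3] else g[5]
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[tok] <- if (is.na(counts[tok])) n else counts[tok] + n
    names(counts)[is.na(names(counts))] <- tok
  }
  as_composition(counts)
}

#' Monoisotopic mass of a composition
#'
#' Sum over tokens of count times the lightest-isotope exact mass;
#' fixed-isotope pseudo-elements contribute their single fixed mass.
#'
#' @param comp An \code{elem_comp} (or anything [as_composition()] accepts).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(composition(H = 2, O = 1))  # 18.0106
#' @export
monoisotopic_mass <- function(comp) {
  comp <- as_composition(comp)
  if (!length(comp)) return(0)
  bad <- setdiff(names(comp), names(.nq_catalog))
  if (length(bad))
    stop("unknown element token(s): ", paste(bad, collapse = ", "))
  sum(vapply(names(comp), function(t) .nq_catalog[[t]]$mass[1], numeric(1)) *
        as.numeric(comp))
}

#' m/z of a charged species
#'
#' \code{(neutral_mass + charge * PROTON_MASS) / charge} with the package's
#' proton-mass convention (1.0072765 Da; electron mass not tracked).
#'
#' @param neutral_mass Neutral monoisotopic mass, Da.
#' @param charge Positive integer charge.
#' @return m/z.
#' @examples
#' mz(1340.6625, 3)  # ~447.89, nitrated angiotensin I (+3)
#' @export
mz <- function(neutral_mass, charge) {
  if (any(charge <= 0) || any(charge != round(charge)))
    stop("charge must be a positive integer")
  (neutral_mass + charge * PROTON_MASS) / charge
}
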