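## Residue compositions (monoisotopic residue = amino acid minus water).
.nq_residues <- local({
  r <- list(
    G = c(C = 2, H = 3, N = 1, O = 1),
    A = c(C = 3, H = 5, N = 1, O = 1),
    S = c(C = 3, H = 5, N = 1, O = 2),
    P = c(C = 5, H = 7, N = 1, O = 1),
    V = c(C = 5, H = 9, N = 1, O = 1),
    T = c(C = 4, H = 7, N = 1, O = 2),
    C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
    L = c(C = 6, H = 11, N = 1, O = 1),
    I = c(C = 6, H = 11, N = 1, O = 1),
    N = c(C = 4, H = 6, N = 2, O = 2),
    D = c(C = 4, H = 5, N = 1, O = 3),
    Q = c(C = 5, H = 8, N = 2, O = 2),
    K = c(C = 6, H = 12, N = 2, O = 1),
    E = c(C = 5, H = 7, N = 1, O = 3),
    M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
    H = c(C = 6, H = 7, N = 3, O = 1),
    F = c(C = 9, H = 9, N = 1, O = 1),
    R = c(C = 6, H = 12, N = 4, O = 1),
    Y = c(C = 9, H = 9, N = 1, O = 2),
    W = c(C = 11, H = 10, N = 2, O = 1)
  )
  lapply(r, as_composition)
})

.nq_water <- composition(H = 2, O = 1)
.nq_CO <- composition(C = 1, O = 1)

#' Define a post-translational modification
#'
#' A modification is represented as a pair of compositions (atoms added,
#' atoms removed) rather than a bare delta mass, so that isotope
#' fine-structure simulation of modified species stays exact, plus the set
#' of residues it may sit on.
#'
#' @param name Modification name.
#' @param add,remove Compositions added/removed.
#' @param targets Character vector of one-letter residue codes.
#' @return A \code{ptm} object.
#' @export
modification <- function(name, add = composition(), remove = composition(),
                         targets) {
  structure(list(name = name, add = as_composition(add),
                 remove = as_composition(remove),
                 targets = targets),
            class = "ptm")
}

#' Built-in modifications
#'
#' \describe{
#'   \item{nitro_light}{Tyrosine nitration by natural-abundance
#'     peroxynitrite: +NO2, -H on Y (delta +44.9851 Da).}
#'   \item{nitro_heavy}{Nitration by 15N-labeled peroxynitrite (O15NOO-):
#'     +15NO2, -H on Y; exactly 0.9970349 Da above the light form.}
#'   \item{cam}{Carbamidomethylation of cysteine (+C2H3NO), the standard
#'     alkylation fixed modification.}
#' }
#'
#' @param name One of \code{"nitro_light"}, \code{"nitro_heavy"}, \code{"cam"}.
#' @return A \code{ptm} object.
#' @examples
#' m <- builtin_modification("nitro_light")
#' monoisotopic_mass(m$add) - monoisotopic_mass(m$remove)  # 44.9851
#' @export
builtin_modification <- function(name) {
  switch(name,
    nitro_light = modification("nitro_light",
                               add = composition(N = 1, O = 2),
                               remove = composition(H = 1), targets = "Y"),
    nitro_heavy = modification("nitro_heavy",
                               add = composition(N15 = 1, O = 2),
                               remove = composition(H = 1), targets = "Y"),
    cam = modification("cam", add = composition(C = 2, H = 3, N = 1, O = 1),
                       targets = "C"),
    stop("unknown modification: ", name)
  )
}

#' Delta mass of a modification
#' @param mod A \code{ptm} object or builtin name.
#' @return Mass shift in Da.
#' @export
modification_delta <- function(mod) {
  if (is.character(mod)) mod <- builtin_modification(mod)
  monoisotopic_mass(mod$add) - monoisotopic_mass(mod$remove)
}

#' Construct a peptide with modifications
#'
#' @param sequence One-letter amino-acid string.
#' @param mods List of modifications, each \code{list(pos = <1-based index>,
#'   mod = <ptm or builtin name>)}; positions must land on a residue in the
#'   modification's target set.
#' @return A \code{peptide} object.
#' @examples
#' peptide("DRVYIHPFHL", mods = list(list(pos = 4, mod = "nitro_light")))
#' parse_peptide("YLYEIAR 1:nitro_heavy")
#' @export
peptide <- function(sequence, mods = list()) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, names(.nq_residues))
  if (length(bad))
    stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  mods <- lapply(mods, function(m) {
    mod <- if (is.character(m$mod)) builtin_modification(m$mod) else m$mod
    pos <- as.integer(m$pos)
    if (pos < 1 || pos > length(res))
      stop("modification position ", pos, " outside sequence of length ",
           length(res))
    if (!res[pos] %in% mod$targets)
      stop("modification '", mod$name, "' cannot sit on residue '",
           res[pos], "' at position ", pos)
    list(pos = pos, mod = mod)
  })
  structure(list(sequence = sequence, residues = res, mods = mods),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  lab <- x$sequence
  if (length(x$mods)) {
    tags <- vapply(x$mods, function(m) paste0(m$pos, ":", m$mod$name),
                   character(1))
    lab <- paste(lab, paste(tags, collapse = " "))
  }
  cat("<peptide>", lab, "\n")
  invisible(x)
}

#' Parse peptide text notation
#'
#' Grammar: a sequence string followed by whitespace-separated
#' \code{pos:modname} tags, e.g. \code{"YICDNQDTISSK 1:nitro_heavy 3:cam"}.
#'
#' @param text Notation string.
#' @return A \code{peptide} object.
#' @export
parse_peptide <- function(text) {
  parts <- strsplit(trimws(text), "\\s+")[[1]]
  if (!length(parts)) stop("empty peptide notation")
  mods <- lapply(parts[-1], function(tag) {
    g <- regmatches(tag, regexec("^([0-9]+):([A-Za-z0-9_]+)$", tag))[[1]]
    if (!length(g))
      stop("cannot parse modification tag '", tag,
           "' (expected pos:modname) at position ",
           which(parts == tag)[1])
    list(pos = as.integer(g[2]), mod = g[3])
  })
  peptide(parts[1], mods = mods)
}

#' Elemental composition of a (modified) peptide
#'
#' Sum of residue compositions plus water, with each modification's added
#' atoms added and removed atoms subtracted.
#'
#' @param pep A \code{peptide} (or notation string).
#' @return An \code{elem_comp}.
#' @export
peptide_composition <- function(pep) {
  if (is.character(pep)) pep <- parse_peptide(pep)
  comp <- Reduce(comp_add, .nq_residues[pep$residues], .nq_water)
  for (m in pep$mods) {
    comp <- comp_add(comp, m$mod$add)
    comp <- comp_subtract(comp, m$mod$remove)
  }
  comp
}

#' Neutral monoisotopic mass of a peptide
#' @inheritParams peptide_composition
#' @return Mass in Da.
#' @export
peptide_mass <- function(pep) monoisotopic_mass(peptide_composition(pep))

.nq_ion <- function(comp, charge, kind) {
  structure(list(composition = comp, charge = as.integer(charge),
                 kind = kind,
                 mz = mz(monoisotopic_mass(comp), charge)),
            class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion> %s%+d  m/z %.4f\n", x$kind, x$charge, x$mz))
  invisible(x)
}

#' Immonium ion of a residue
#'
#' The immonium ion is the internal fragment H2N+=CH-R from double
#' backbone cleavage: residue composition minus CO, singly charged. With
#' the nitro modifications this yields the nitrotyrosine reporter ions at
#' m/z 181.0608 (light) and 182.0578 (heavy).
#'
#' @param residue One-letter code.
#' @param mods List of \code{ptm} objects or builtin names applied to the
#'   residue.
#' @return An \code{ion_species} (charge 1).
#' @examples
#' immonium_ion("Y")$mz                  # 136.0757
#' immonium_ion("Y", "nitro_light")$mz   # 181.0608
#' immonium_ion("Y", "nitro_heavy")$mz   # 182.0578
#' @export
immonium_ion <- function(residue, mods = list()) {
  if (!residue %in% names(.nq_residues))
    stop("unknown residue: ", residue)
  if (is.character(mods)) mods <- as.list(mods)
  comp <- comp_subtract(.nq_residues[[residue]], .nq_CO)
  for (m in mods) {
    if (is.character(m)) m <- builtin_modification(m)
    if (!residue %in% m$targets)
      stop("modification '", m$name, "' cannot sit on residue '", residue, "'")
    comp <- comp_subtract(comp_add(comp, m$add), m$remove)
  }
  .nq_ion(comp, 1L, "immonium")
}

#' Reporter-ion m/z constants
#'
#' The light and heavy nitrotyrosine immonium reporter m/z values,
#' computed from composition (not hard-coded).
#' @return Named numeric vector with elements \code{light}, \code{heavy}.
#' @export
reporter_mz <- function() {
  c(light = immonium_ion("Y", "nitro_light")$mz,
    heavy = immonium_ion("Y", "nitro_heavy")$mz)
}

#' Backbone fragment ions of a peptide
#'
#' Generates b/y/a series ions at charges 1..\code{max_charge}.
#' Conventions: the b ion neutral is the prefix residue sum; y is the
#' suffix residue sum plus water; a = b - CO. Modification deltas are
#' carried by fragments containing the modified position, so
#' nitrotyrosine-containing b/y fragments of a light/heavy pair show the
#' 0.9970349/z doublet spacing.
#'
#' @param pep A \code{peptide} (or notation string).
#' @param series Subset of \code{c("b", "y", "a")}.
#' @param max_charge Maximum fragment charge.
#' @return Data frame with columns \code{series}, \code{index},
#'   \code{charge}, \code{mz}.
#' @export
fragment_ions <- function(pep, series = c("b", "y"), max_charge = 1L) {
  if (is.character(pep)) pep <- parse_peptide(pep)
  series <- match.arg(series, c("b", "y", "a"), several.ok = TRUE)
  n <- length(pep$residues)
  modpos <- vapply(pep$mods, `[[`, integer(1), "pos")
  frag_comp <- function(idx) {
    comp <- Reduce(comp_add, .nq_residues[pep$residues[idx]], composition())
    for (m in pep$mods[modpos %in% idx]) {
      comp <- comp_subtract(comp_add(comp, m$mod$add), m$mod$remove)
    }
    comp
  }
  rows <- list()
  for (i in seq_len(n - 1)) {
    pre <- frag_comp(seq_len(i))
    suf <- frag_comp(seq(n - i + 1, n))
    for (z in seq_len(max_charge)) {
      if ("b" %in% series)
        rows[[length(rows) + 1L]] <- data.frame(
          series = "b", index = i, charge = z,
          mz = mz(monoisotopic_mass(pre), z))
      if ("a" %in% series)
        rows[[length(rows) + 1L]] <- data.frame(
          series = "a", index = i, charge = z,
          mz = mz(monoisotopic_mass(comp_subtract(pre, .nq_CO)), z))
      if ("y" %in% series)
        rows[[length(rows) + 1L]] <- data.frame(
          series = "y", index = i, charge = z,
          mz = mz(monoisotopic_mass(comp_add(suf, .nq_water)), z))
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$series, out$index, out$charge), , drop = FALSE]
}
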