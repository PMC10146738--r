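# Group-contribution solubility parameters after Hoftyzer-Van Krevelen:
#   delta_d = sum(Fd) / V,  delta_p = sqrt(sum(Fp^2)) / V,
#   delta_h = sqrt(sum(Eh) / V),  delta_t = sqrt(dd^2 + dp^2 + dh^2),
# with V the molar volume from Fedors group increments (no measured
# densities are required). Fd/Fp in (MJ/m^3)^(1/2) cm^3/mol, Eh in J/mol,
# V in cm^3/mol, deltas in (MJ/m^3)^(1/2) = MPa^(1/2).

.hvk_table <- tibble::tribble(
  ~group,       ~Fd,  ~Fp,  ~Eh,    ~Vg,
  "phenylene",  1270, 110,  0,      52.4,
  "-COOH",      530,  420,  10000,  28.5,
  "-COO-",      390,  490,  7000,   18.0,
  "-OH",        210,  500,  20000,  10.0,
  "-NH2",       280,  0,    8400,   19.2,
  "-O-",        100,  400,  3000,   3.8,
  "-CH3",       420,  0,    0,      33.5,
  "-CH2-",      270,  0,    0,      16.1
)

# Fragmentation of the nine drugs: a para/ortho/meta-disubstituted benzene
# ring enters as one phenylene unit; methoxy as -O- plus -CH3; esters as
# -COO- plus the alkyl chain. The three methoxybenzoic acid isomers share
# one multiset (group methods cannot distinguish substitution position).
.drug_groups <- tibble::tribble(
  ~drug,    ~group,       ~count,
  "PHBA",   "phenylene",  1L,  "PHBA",  "-COOH", 1L,  "PHBA",  "-OH",   1L,
  "MPDB",   "phenylene",  1L,  "MPDB",  "-COO-", 1L,  "MPDB",  "-CH3",  1L,  "MPDB", "-OH",  1L,
  "PABA",   "phenylene",  1L,  "PABA",  "-COOH", 1L,  "PABA",  "-NH2",  1L,
  "MPAB",   "phenylene",  1L,  "MPAB",  "-COO-", 1L,  "MPAB",  "-CH3",  1L,  "MPAB", "-NH2", 1L,
  "EPAB",   "phenylene",  1L,  "EPAB",  "-COO-", 1L,  "EPAB",  "-CH2-", 1L,  "EPAB", "-CH3", 1L,  "EPAB", "-NH2", 1L,
  "BPAB",   "phenylene",  1L,  "BPAB",  "-COO-", 1L,  "BPAB",  "-CH2-", 3L,  "BPAB", "-CH3", 1L,  "BPAB", "-NH2", 1L,
  "2-MBA",  "phenylene",  1L,  "2-MBA", "-COOH", 1L,  "2-MBA", "-O-",   1L,  "2-MBA", "-CH3", 1L,
  "3-MBA",  "phenylene",  1L,  "3-MBA", "-COOH", 1L,  "3-MBA", "-O-",   1L,  "3-MBA", "-CH3", 1L,
  "4-MBA",  "phenylene",  1L,  "4-MBA", "-COOH", 1L,  "4-MBA", "-O-",   1L,  "4-MBA", "-CH3", 1L
)

#' Hoftyzer-Van Krevelen group-contribution table
#'
#' Reference-book constants: dispersion and polar molar attraction
#' functions `Fd`, `Fp` in (MJ/m^3)^(1/2) cm^3/mol, hydrogen-bond cohesion
#' energy `Eh` in J/mol, and Fedors molar-volume increments `Vg` in
#' cm^3/mol.
#'
#' @return A tibble with columns `group`, `Fd`, `Fp`, `Eh`, `Vg`.
#' @export
hvk_group_table <- function() .hvk_table

#' Shipped group multisets for the nine reference drugs
#'
#' @param drug Optional drug label to filter on (e.g. `"PHBA"`).
#' @return A tibble with columns `drug`, `group`, `count`.
#' @export
#' @examples
#' hvk_drug_groups("PHBA")
hvk_drug_groups <- function(drug = NULL) {
  out <- .drug_groups
  if (!is.null(drug)) {
    if (!all(drug %in% out$drug)) {
      stop_lookup(sprintf(
        "Unknown drug label(s): %s.",
        paste(setdiff(drug, out$drug), collapse = ", ")
      ))
    }
    out <- out[out$drug %in% drug, , drop = FALSE]
  }
  out
}

normalize_groups <- function(groups) {
  if (is.character(groups) && length(groups) == 1L) {
    groups <- hvk_drug_groups(groups)[c("group", "count")]
  }
  if (!is.data.frame(groups) || !all(c("group", "count") %in% names(groups))) {
    stop_validation("`groups` must be a drug label or a data frame with columns `group`, `count`.")
  }
  if (any(groups$count <= 0) || any(groups$count != as.integer(groups$count))) {
    stop_validation("Group counts must be positive integers.")
  }
  groups
}

lookup_groups <- function(groups, table) {
  idx <- match(groups$group, table$group)
  if (anyNA(idx)) {
    stop_lookup(sprintf(
      "Group label(s) not in the contribution table: %s.",
      paste(unique(groups$group[is.na(idx)]), collapse = ", ")
    ))
  }
  cbind(groups, table[idx, c("Fd", "Fp", "Eh", "Vg")])
}

#' Molar volume from Fedors group increments
#'
#' @param groups A drug label among the nine shipped drugs, or a data
#'   frame with columns `group` and `count`.
#' @param table Group-contribution table (default [hvk_group_table()]).
#' @return Molar volume in cm^3/mol.
#' @export
#' @examples
#' molar_volume("PHBA")
molar_volume <- function(groups, table = hvk_group_table()) {
  groups <- normalize_groups(groups)
  if (nrow(groups) == 0L) return(0)
  g <- lookup_groups(groups, table)
  sum(g$count * g$Vg)
}

#' Solubility-parameter components from group contributions
#'
#' @inheritParams molar_volume
#' @return Named numeric vector `c(delta_d, delta_p, delta_h)` in
#'   (MJ/m^3)^(1/2).
#' @export
delta_components <- function(groups, table = hvk_group_table()) {
  groups <- normalize_groups(groups)
  g <- lookup_groups(groups, table)
  V <- sum(g$count * g$Vg)
  if (V <= 0) stop_domain("Molar volume must be positive.")
  c(
    delta_d = sum(g$count * g$Fd) / V,
    delta_p = sqrt(sum(g$count * g$Fp^2)) / V,
    delta_h = sqrt(sum(g$count * g$Eh) / V)
  )
}

#' Total solubility parameter from its components
#'
#' \eqn{\delta_t = \sqrt{\delta_d^2 + \delta_p^2 + \delta_h^2}}.
#'
#' @param delta_d,delta_p,delta_h Non-negative components in
#'   (MJ/m^3)^(1/2). `delta_d` may also be a length-3 vector holding all
#'   three components.
#' @return Total solubility parameter in (MJ/m^3)^(1/2).
#' @export
#' @examples
#' total_delta(3, 4, 0)
total_delta <- function(delta_d, delta_p = NULL, delta_h = NULL) {
  if (is.null(delta_p) && is.null(delta_h) && length(delta_d) == 3L) {
    delta_p <- delta_d[[2L]]
    delta_h <- delta_d[[3L]]
    delta_d <- delta_d[[1L]]
  }
  comps <- c(delta_d, delta_p, delta_h)
  if (length(comps) != 3L || any(!is.finite(comps))) {
    stop_domain("total_delta needs three finite components.")
  }
  if (any(comps < 0)) stop_domain("Solubility-parameter components must be non-negative.")
  sqrt(sum(comps^2))
}

#' Hoftyzer-Van Krevelen solubility parameters for a molecule
#'
#' Computes the dispersion, polar, hydrogen-bond and total solubility
#' parameters for a molecule described as a multiset of group fragments.
#'
#' @inheritParams molar_volume
#' @param drug_id Optional label attached to the result; defaults to the
#'   drug label when `groups` is one of the shipped drugs.
#' @return One-row tibble with `drug` (if labelled), `delta_d`, `delta_p`,
#'   `delta_h`, `delta_t` in (MJ/m^3)^(1/2) and `molar_volume` in
#'   cm^3/mol.
#' @export
#' @examples
#' hvk_parameters("PABA")
hvk_parameters <- function(groups, table = hvk_group_table(), drug_id = NULL) {
  if (is.character(groups) && length(groups) == 1L && is.null(drug_id)) {
    drug_id <- groups
  }
  comps <- delta_components(groups, table)
  out <- tibble(
    delta_d = comps[["delta_d"]],
    delta_p = comps[["delta_p"]],
    delta_h = comps[["delta_h"]],
    delta_t = total_delta(comps),
    molar_volume = molar_volume(groups, table)
  )
  if (!is.null(drug_id)) out <- dplyr::mutate(out, drug = drug_id, .before = 1L)
  out
}
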