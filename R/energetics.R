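# MM/PBSA bookkeeping over per-residue component tables:
#   G_total = E_MM + G_sol - T.dS,   E_MM = E_ele + E_vdw,
#   G_sol = G_polar + G_np,          G_np = gamma * SASA + beta.
# No MD engine: the module consumes component tables and performs the
# additive decomposition per residue.

#' Nonpolar solvation term from SASA
#'
#' Linear model \code{G_np = gamma * SASA + beta} with the standard
#' coefficients gamma = 0.0054 kcal/mol/A^2 and beta = 0.92 kcal/mol.
#'
#' @param sasa solvent-accessible surface area in A^2 (>= 0).
#' @param gamma surface-tension coefficient (kcal/mol/A^2).
#' @param beta intercept (kcal/mol).
#' @return Nonpolar solvation free energy in kcal/mol.
#' @export
nonpolar_energy <- function(sasa, gamma = 0.0054, beta = 0.92) {
  if (any(sasa < 0)) stop("SASA must be non-negative")
  gamma * sasa + beta
}

#' Combine per-residue energy components
#'
#' Accepts a table with per-residue \code{E_ele}, \code{E_vdw},
#' \code{G_polar} and exactly one of \code{G_np} or \code{SASA} (SASA is
#' converted through \code{\link{nonpolar_energy}}), and computes
#' \code{E_MM = E_ele + E_vdw}, \code{G_sol = G_polar + G_np} and
#' \code{G_total = E_MM + G_sol - TdS}. A total-system row (sums over
#' residues; the entropy term charged once) is appended.
#'
#' @param components \code{data.frame} with a \code{residue} column and the
#'   component columns above.
#' @param gamma,beta nonpolar coefficients (used when \code{SASA} is given).
#' @param tds fixed entropy term T.dS in kcal/mol (default 0: the entropy
#'   change is not computed, only carried as a constant).
#' @return \code{data.frame}: \code{residue}, \code{E_MM}, \code{G_polar},
#'   \code{G_np}, \code{G_total}; last row \code{"TOTAL"}.
#' @export
combine_energy <- function(components, gamma = 0.0054, beta = 0.92, tds = 0) {
  need <- c("residue", "E_ele", "E_vdw", "G_polar")
  miss <- setdiff(need, names(components))
  if (length(miss)) stop("missing component field(s): ",
                         paste(miss, collapse = ", "))
  has_np <- "G_np" %in% names(components)
  has_sasa <- "SASA" %in% names(components)
  if (has_np == has_sasa) {
    stop("exactly one of G_np or SASA must be provided")
  }
  g_np <- if (has_np) components$G_np else
    nonpolar_energy(components$SASA, gamma, beta)
  e_mm <- components$E_ele + components$E_vdw
  g_total <- e_mm + components$G_polar + g_np - tds
  rows <- data.frame(residue = as.character(components$residue),
                     E_MM = e_mm, G_polar = components$G_polar,
                     G_np = g_np, G_total = g_total,
                     stringsAsFactors = FALSE)
  total <- data.frame(residue = "TOTAL", E_MM = sum(e_mm),
                      G_polar = sum(components$G_polar), G_np = sum(g_np),
                      G_total = sum(e_mm) + sum(components$G_polar) +
                        sum(g_np) - tds,
                      stringsAsFactors = FALSE)
  out <- rbind(rows, total)
  attr(out, "tds") <- tds
  out
}

#' Flag residues as favorable or unfavorable binders
#'
#' A residue's contribution is favorable iff its total binding free energy
#' is strictly negative; exactly zero is flagged unfavorable by convention.
#'
#' @param rows decomposition rows from \code{\link{combine_energy}}.
#' @return The rows with a \code{favorability} column
#'   (\code{"favorable"}/\code{"unfavorable"}).
#' @export
energy_favorability <- function(rows) {
  rows$favorability <- ifelse(rows$G_total < 0, "favorable", "unfavorable")
  rows
}

#' Read a per-residue energy component TSV
#' @param file TSV with columns \code{residue}, \code{E_ele}, \code{E_vdw},
#'   \code{G_polar} and \code{G_np} or \code{SASA}.
#' @return \code{data.frame} of components.
#' @export
read_energy_table <- function(file) read_tsv(file)
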