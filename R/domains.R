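#' Protein domain tables and residue mapping
#'
#' A domain table is a data.frame with columns `domain` (name),
#' `start` and `end` (1-based inclusive residue coordinates). The default
#' table describes the six functional domains of the 3418-residue human
#' BRCA2 protein. Only the P/CAF-binding interval (residues 290-453) has an
#' exact published span among the regions this package needs to reason
#' about; the remaining coordinates are the canonical literature positions
#' (PALB2-binding N-terminal helix, the BRC repeat region, the DNA-binding
#' helical domain and OB folds, and the C-terminal TR2/RAD51-binding
#' segment).
#'
#' @return A data.frame domain table.
#' @examples
#' truncation_retained_domains(871, brca2_domains())
#' @export
brca2_domains <- function() {
  data.frame(
    domain = c("PALB2 binding", "P/CAF binding", "BRC repeats",
               "Helical domain", "OB folds", "TR2"),
    start = c(21L, 290L, 1002L, 2481L, 2670L, 3270L),
    end   = c(39L, 453L, 2085L, 2667L, 3190L, 3305L),
    stringsAsFactors = FALSE
  )
}

validate_domain_table <- function(domains) {
  stopifnot(is.data.frame(domains),
            all(c("domain", "start", "end") %in% names(domains)))
  if (nrow(domains) &&
      any(domains$start < 1L | domains$end < domains$start))
    stop("domain table requires 1 <= start <= end")
  domains
}

#' Domains retained by a premature stop
#'
#' A stop-gain at residue `stop_residue` truncates translation so that
#' residues `1..(stop_residue - 1)` are produced. Domains ending strictly
#' before the stop are fully retained; domains straddling the stop are
#' reported separately as partial.
#'
#' @param stop_residue 1-based residue of the premature stop codon.
#' @param domains A domain table (default [brca2_domains()]).
#' @return List with character vectors `retained` and `partial`.
#' @export
truncation_retained_domains <- function(stop_residue,
                                        domains = brca2_domains()) {
  stopifnot(length(stop_residue) == 1L, stop_residue >= 1L)
  domains <- validate_domain_table(domains)
  if (!nrow(domains)) return(list(retained = character(), partial = character()))
  list(
    retained = domains$domain[domains$end < stop_residue],
    partial  = domains$domain[domains$start < stop_residue &
                                domains$end >= stop_residue]
  )
}

#' Locate a residue within a domain table
#'
#' @param residue 1-based residue position.
#' @param domains A domain table (default [brca2_domains()]).
#' @return Character vector of all domains with `start <= residue <= end`
#'   (empty if the residue falls between domains).
#' @export
locate_in_domain <- function(residue, domains = brca2_domains()) {
  stopifnot(length(residue) == 1L, residue >= 1L)
  domains <- validate_domain_table(domains)
  domains$domain[domains$start <= residue & domains$end >= residue]
}
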