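#' Reference clock-factor query set
#'
#' The 23 clock-associated proteins used as search queries: the
#' Synechococcus elongatus PCC 7942 core factors (KaiA, KaiB, KaiC), the
#' three diverged KaiB and KaiC paralog subgroups of Synechocystis sp.
#' PCC 6803 (KaiB1-3, KaiC1-3), the clock-input factors (Pex, LdpA, PrkE,
#' NhtA, IrcA, CdpA) and the output factors (SasA, LabA, LalA, CpmA, Crm,
#' RpaA, RpaB, plus CikA, which acts in both input and output).
#'
#' @return Character vector of 23 factor labels.
#' @export
clock_queries <- function() {
  c("KaiA", "KaiB", "KaiC",
    "KaiB1", "KaiB2", "KaiB3", "KaiC1", "KaiC2", "KaiC3",
    "Pex", "LdpA", "PrkE", "NhtA", "IrcA", "CdpA",
    "SasA", "LabA", "LalA", "CpmA", "Crm", "RpaA", "RpaB", "CikA")
}

#' Default factor merge map
#'
#' The Synechococcus 7942 KaiB and KaiC queries are collapsed onto the
#' Synechocystis 6803 KaiB1/KaiC1 subgroups they are most similar to, so the
#' co-occurrence analysis runs over 21 factor labels. The map is configurable
#' because the exact merge underlying the 21-factor set is a modelling
#' choice, not a property of the data.
#'
#' @return Named character vector mapping query labels to merged labels.
#' @export
default_factor_merge <- function() {
  c(KaiB = "KaiB1", KaiC = "KaiC1")
}

#' Clock factors after merging
#'
#' @param merge_map Named character vector as in [default_factor_merge()].
#' @return Character vector of merged factor labels (21 by default).
#' @export
clock_factors <- function(merge_map = default_factor_merge()) {
  f <- clock_queries()
  mapped <- merge_map[f]
  unique(ifelse(is.na(mapped), f, mapped))
}

#' KaiC-family factor labels
#'
#' Strains are retained in the inventory only if they carry at least one
#' KaiC-family homolog, because KaiC is the core of the oscillator.
#'
#' @return Character vector of KaiC-family labels.
#' @export
kaic_family <- function() {
  c("KaiC", "KaiC1", "KaiC2", "KaiC3")
}
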