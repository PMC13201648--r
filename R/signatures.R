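#' Built-in breast cancer gene signatures
#'
#' The four fixed gene panels used throughout the pipeline:
#' * `era_induced` (21 genes): estrogen-induced genes from preclinical ER+
#'   models; their mean z-score is the ERalpha activity score.
#' * `era_repressed` (17 genes): estrogen-repressed genes; scored separately,
#'   never subtracted from the induced score.
#' * `luminal_tf` (15 genes): transcription factors enriched in luminal vs
#'   basal breast cancer; loss of expression marks lineage plasticity.
#' * `mapk_target` (9 genes): MAPK pathway target genes, an
#'   ERalpha-independent proliferative program.
#'
#' @return A named list of character vectors of gene symbols.
#' @examples
#' lengths(breast_signatures())
#' @export
breast_signatures <- function() {
  list(
    era_induced = c(
      "OLFM1", "NXPH3", "AMZ1", "CELSR2", "CT62", "RBM24", "FKBP4", "SGK3",
      "PPM1J", "FMN1", "IGFBP4", "AREG", "RAPGEFL1", "PGR", "RET", "TFF1",
      "ZNF703", "RERG", "SLC9A3R1", "GREB1", "NOS1AP"
    ),
    era_repressed = c(
      "STON1", "EGLN3", "FAM171B", "LIPH", "SSPO", "BAMBI", "NBEA", "GRM4",
      "PNPLA7", "DDIT4", "TP53INP2", "TGFB3", "PSCA", "BCAS1", "CCNG2",
      "TP53INP1", "SEMA3E"
    ),
    luminal_tf = c(
      "XBP1", "ESR1", "FOXA1", "ZNF552", "PGR", "RARA", "GATA3", "CXXC5",
      "AR", "DACH1", "ZNF703", "ZNF467", "SPDEF", "ZBTB42", "CREB3L4"
    ),
    mapk_target = c(
      "SPRY2", "SPRY4", "ETV4", "ETV5", "DUSP4", "DUSP6", "CCND1", "EPHA2",
      "EPHA4"
    )
  )
}

#' Built-in clinical variant panel
#'
#' Hotspot variants screened when inferring mutation status from RNA-seq
#' pileups: the ESR1 ligand-binding-domain panel (E380Q, S463P, V534E, P535H,
#' L536H/P/R/Q, Y537N/S/C, D538G) and the PIK3CA panel (C420R, E542K,
#' E545K/G, Q546K, M1043I, H1047Y/R/L).
#'
#' @return A tibble with columns `gene` and `variant` (formatted
#'   `GENE:CHANGE`).
#' @examples
#' dplyr::count(variant_panel(), gene)
#' @export
variant_panel <- function() {
  esr1 <- c("E380Q", "S463P", "V534E", "P535H", "L536H", "L536P", "L536R",
            "L536Q", "Y537N", "Y537S", "Y537C", "D538G")
  pik3ca <- c("C420R", "E542K", "E545K", "E545G", "Q546K", "M1043I",
              "H1047Y", "H1047R", "H1047L")
  tibble::tibble(
    gene = c(rep("ESR1", length(esr1)), rep("PIK3CA", length(pik3ca))),
    variant = c(paste0("ESR1:", esr1), paste0("PIK3CA:", pik3ca))
  )
}
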