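#' Default 72-gene panel
#'
#' The default targeted panel: 50 subtype (PAM50) genes, 17 immune genes and
#' 5 housekeeping genes. Each subtype gene carries a signature annotation
#' (`luminal`, `proliferation`, `her2`, `basal`, `other`) used by the
#' synthetic-cohort generator to build subtype-specific mean profiles, and a
#' baseline log2 relative-abundance used as the generator's per-gene
#' intercept. The 17 immune gene identities are a documented placeholder
#' convention (canonical T-cell/cytotoxicity/chemokine markers); all
#' downstream computation is list-agnostic and a custom panel can be given
#' wherever a panel is accepted.
#'
#' @return data.frame with columns `gene`, `role`, `signature`,
#'   `baseline_log2`.
#' @examples
#' table(defaultGenePanel()$role)
#' @export
defaultGenePanel <- function() {
  sig <- c(
    ACTR3B = "basal",   ANLN = "proliferation", BAG1 = "luminal",
    BCL2 = "luminal",   BIRC5 = "proliferation", BLVRA = "luminal",
    CCNB1 = "proliferation", CCNE1 = "proliferation",
    CDC20 = "proliferation", CDC6 = "proliferation", CDH3 = "basal",
    CENPF = "proliferation", CEP55 = "proliferation", CXXC5 = "luminal",
    EGFR = "basal",     ERBB2 = "her2", ESR1 = "luminal",
    EXO1 = "proliferation", FGFR4 = "her2", FOXA1 = "luminal",
    FOXC1 = "basal",    GPR160 = "luminal", GRB7 = "her2",
    KIF2C = "proliferation", KRT14 = "basal", KRT17 = "basal",
    KRT5 = "basal",     MAPT = "luminal", MDM2 = "luminal",
    MELK = "proliferation", MIA = "basal", MKI67 = "proliferation",
    MLPH = "luminal",   MMP11 = "other", MYBL2 = "proliferation",
    MYC = "basal",      NAT1 = "luminal", NDC80 = "proliferation",
    NUF2 = "proliferation", ORC6 = "proliferation", PGR = "luminal",
    PHGDH = "basal",    PTTG1 = "proliferation", RRM2 = "proliferation",
    SFRP1 = "basal",    SLC39A6 = "luminal", TMEM45B = "luminal",
    TYMS = "proliferation", UBE2C = "proliferation", UBE2T = "proliferation")
  immune <- c("CD2", "CD3D", "CD3E", "CD8A", "CD27", "CD48", "CCL5",
              "CXCL9", "CXCL10", "CXCL13", "GZMA", "GZMB", "GZMK",
              "PRF1", "IFNG", "IDO1", "PDCD1")
  hk <- c("ACTB", "GAPDH", "GUSB", "RPLP0", "TFRC")
  genes <- c(names(sig), immune, hk)
  role <- c(rep("subtype", length(sig)), rep("immune", length(immune)),
            rep("housekeeping", length(hk)))
  signature <- c(unname(sig), rep("immune", length(immune)),
                 rep("housekeeping", length(hk)))
  base_by_sig <- c(luminal = 7, proliferation = 6, her2 = 6, basal = 5.5,
                   other = 6, immune = 5, housekeeping = 9)
  # small fixed per-gene stagger so no two genes are forced identical
  baseline <- base_by_sig[signature] + (seq_along(genes) %% 3) * 0.4
  data.frame(gene = genes, role = role, signature = signature,
             baseline_log2 = unname(baseline), stringsAsFactors = FALSE)
}

#' Proliferation gene subset used by the ROR-P score
#'
#' The 11-gene proliferation subset averaged into the proliferation score P
#' of the proliferation-weighted risk of recurrence. A convention of this
#' package (the panel assay publishes no subset); overridable in
#' [trainCentroids()].
#' @return character vector of gene symbols.
#' @export
proliferationGeneSet <- function() {
  c("BIRC5", "CCNB1", "CDC20", "CEP55", "KIF2C", "MKI67",
    "NDC80", "NUF2", "PTTG1", "RRM2", "UBE2C")
}

#' Read a gene-panel configuration from YAML
#'
#' The YAML file must contain lists `subtype`, `immune` and `housekeeping`
#' of gene symbols; optional `signature` (map gene -> signature) and
#' `baseline_log2` (map gene -> numeric) entries refine the generator's
#' behaviour for custom panels.
#'
#' @param path path to a YAML file.
#' @return data.frame in the format of [defaultGenePanel()].
#' @export
readGenePanelConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("subtype", "immune", "housekeeping")
  if (!all(need %in% names(cfg)))
    stop("gene panel config must list: ", paste(need, collapse = ", "))
  genes <- unlist(cfg[need], use.names = FALSE)
  if (anyDuplicated(genes))
    stop("gene panel lists must be disjoint; duplicated: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  role <- rep(need, lengths(cfg[need]))
  signature <- ifelse(role == "subtype", "other", role)
  if (!is.null(cfg$signature)) {
    sg <- unlist(cfg$signature)
    signature[match(names(sg), genes)] <- unname(sg)
  }
  base_by_sig <- c(luminal = 7, proliferation = 6, her2 = 6, basal = 5.5,
                   other = 6, immune = 5, housekeeping = 9)
  baseline <- unname(base_by_sig[signature])
  if (!is.null(cfg$baseline_log2)) {
    bl <- unlist(cfg$baseline_log2)
    baseline[match(names(bl), genes)] <- unname(bl)
  }
  data.frame(gene = genes, role = role, signature = signature,
             baseline_log2 = baseline, stringsAsFactors = FALSE)
}
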