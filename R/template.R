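#' Default pathway templates for panel simulation
#'
#' Templates describing the composition of a vendor-style global metabolomics
#' panel and a complex-lipid panel: one row per sub-pathway with its
#' super-pathway, member count, panel and imputation class. The global
#' template totals 768 metabolites over nine super-pathways (amino acids 196,
#' carbohydrates 25, cofactors and vitamins 29, energy 10, lipids 259,
#' nucleotides 33, partially characterized molecules 2, peptides 33,
#' xenobiotics 181) and 94 sub-pathways, among them a 7-member Acyl Cholines
#' and an 18-member Androgenic Steroids sub-pathway, eight drug sub-pathways
#' totalling 64 compounds and 6 tobacco metabolites. The lipid template
#' totals 1007 compounds over 11 super-pathways and 19 sub-pathways
#' (cholesterol esters 26, diacylglycerols 58, free fatty acids 25,
#' lysophosphatidylcholines 18, lysophosphatidylethanolamines 17,
#' monoacylglycerols 26, phosphatidylcholines 103, phosphatidylethanolamines
#' 127, phosphatidylinositols 28, sphingolipids 61, triacylglycerols 518).
#'
#' Sub-pathway names that a published panel does not enumerate are filled
#' with representative labels from the vendor's public vocabulary; member
#' counts for those fillers are plausible placeholders chosen so the
#' super-pathway totals and the sub-pathway count match the panel dimensions
#' above.
#'
#' @param panel `"global"` or `"lipid"`.
#' @return data.frame with columns `sub_pathway`, `super_pathway`,
#'   `n_members`, `panel`, `imputation_class`.
#' @examples
#' sum(defaultTemplate("global")$n_members)   # 768
#' sum(defaultTemplate("lipid")$n_members)    # 1007
#' @export
defaultTemplate <- function(panel = c("global", "lipid")) {
  panel <- match.arg(panel)
  if (panel == "global") tpl <- .globalTemplate() else tpl <- .lipidTemplate()
  tpl$panel <- panel
  tpl$imputation_class <- classifyImputation(tpl$sub_pathway)
  tpl
}

.tplRows <- function(super, ...) {
  xs <- list(...)
  data.frame(sub_pathway = vapply(xs, `[[`, character(1), 1),
             super_pathway = super,
             n_members = vapply(xs, function(x) as.integer(x[[2]]), integer(1)),
             stringsAsFactors = FALSE)
}

.globalTemplate <- function() {
  rbind(
    .tplRows("Amino Acids",
      list("Glycine, Serine and Threonine Metabolism", 12),
      list("Alanine and Aspartate Metabolism", 8),
      list("Glutamate Metabolism", 10),
      list("Histidine Metabolism", 12),
      list("Lysine Metabolism", 12),
      list("Phenylalanine Metabolism", 8),
      list("Tyrosine Metabolism", 14),
      list("Tryptophan Metabolism", 14),
      list("Leucine, Isoleucine and Valine Metabolism", 22),
      list("Methionine, Cysteine, SAM and Taurine Metabolism", 16),
      list("Urea Cycle; Arginine and Proline Metabolism", 14),
      list("Creatine Metabolism", 3),
      list("Polyamine Metabolism", 6),
      list("Guanidino and Acetamido Metabolism", 4),
      list("Glutathione Metabolism", 6),
      list("Betaine Metabolism", 4),
      list("Tyramine Metabolism", 3),
      list("Indole Derivatives", 5),
      list("Imidazole Metabolism", 4),
      list("Sulfur Amino Acid Metabolism", 5),
      list("Aromatic Amino Acid Derivatives", 5),
      list("D-Amino Acids", 4),
      list("N-Acetyl Amino Acids", 5)),
    .tplRows("Carbohydrates",
      list("Glycolysis, Gluconeogenesis, and Pyruvate Metabolism", 8),
      list("Pentose Metabolism", 6),
      list("Fructose, Mannose and Galactose Metabolism", 4),
      list("Disaccharides and Oligosaccharides", 1),
      list("Aminosugar Metabolism", 3),
      list("Glycogen Metabolism", 3)),
    .tplRows("Cofactors and Vitamins",
      list("Nicotinate and Nicotinamide Metabolism", 6),
      list("Riboflavin Metabolism", 3),
      list("Pantothenate and CoA Metabolism", 3),
      list("Ascorbate and Aldarate Metabolism", 5),
      list("Tocopherol Metabolism", 4),
      list("Vitamin B6 Metabolism", 2),
      list("Biotin Metabolism", 1),
      list("Vitamin A Metabolism", 5)),
    .tplRows("Energy",
      list("TCA Cycle", 7),
      list("Oxidative Phosphorylation", 3)),
    .tplRows("Lipids",
      list("Acyl Cholines", 7),
      list("Acyl Carnitines", 39),
      list("Fatty Acid Metabolism (Acyl Glutamine)", 1),
      list("Androgenic Steroids", 18),
      list("Progestin Steroids", 6),
      list("Corticosteroids", 4),
      list("Pregnenolone Steroids", 4),
      list("Primary Bile Acid Metabolism", 5),
      list("Secondary Bile Acid Metabolism", 12),
      list("Sterol", 5),
      list("Long Chain Fatty Acid", 19),
      list("Medium Chain Fatty Acid", 8),
      list("Polyunsaturated Fatty Acid (n3 and n6)", 12),
      list("Fatty Acid, Branched", 4),
      list("Fatty Acid, Dicarboxylate", 14),
      list("Fatty Acid, Monohydroxy", 10),
      list("Fatty Acid Metabolism (Acyl Glycine)", 5),
      list("Fatty Acid Synthesis", 3),
      list("Ketone Bodies", 2),
      list("Phospholipid Metabolism", 12),
      list("Lysophospholipid", 16),
      list("Plasmalogen", 6),
      list("Glycerolipid Metabolism", 5),
      list("Diacylglycerol", 4),
      list("Sphingolipid Metabolism", 12),
      list("Endocannabinoid", 8),
      list("Eicosanoid", 6),
      list("Inositol Metabolism", 5),
      list("Carnitine Metabolism", 4),
      list("Mevalonate Metabolism", 3)),
    .tplRows("Nucleotides",
      list("Purine Metabolism, (Hypo)Xanthine/Inosine Containing", 9),
      list("Purine Metabolism, Adenine Containing", 7),
      list("Purine Metabolism, Guanine Containing", 4),
      list("Pyrimidine Metabolism, Cytidine Containing", 4),
      list("Pyrimidine Metabolism, Uracil Containing", 7),
      list("Pyrimidine Metabolism, Thymine Containing", 2)),
    .tplRows("Partially Characterized Molecules",
      list("Partially Characterized Molecules", 2)),
    .tplRows("Peptides",
      list("Dipeptides", 6),
      list("Gamma-glutamyl Amino Acid", 18),
      list("Acetylated Peptides", 5),
      list("Fibrinogen Cleavage Peptides", 4)),
    .tplRows("Xenobiotics",
      list("Bacterial/Fungal", 3),
      list("Benzoate Metabolism", 21),
      list("Chemical", 23),
      list("Food Component/Plant", 49),
      list("Tobacco Metabolites", 6),
      list("Xanthine Metabolism", 15),
      list("Drug - Analgesics, Anesthetics", 20),
      list("Drug - Antibiotics", 8),
      list("Drug - Cardiovascular", 7),
      list("Drug - Neurological", 9),
      list("Drug - Gastrointestinal", 5),
      list("Drug - Metabolic", 6),
      list("Drug - Respiratory", 4),
      list("Drug - Topical Agents", 5)))
}

.lipidTemplate <- function() {
  rbind(
    .tplRows("Cholesterol Esters", list("Cholesterol Esters", 26)),
    .tplRows("Diacylglycerols", list("Diacylglycerols", 58)),
    .tplRows("Free Fatty Acids", list("Free Fatty Acids", 25)),
    .tplRows("Lysophosphatidylcholines", list("Lysophosphatidylcholines", 18)),
    .tplRows("Lysophosphatidylethanolamines",
             list("Lysophosphatidylethanolamines", 17)),
    .tplRows("Monoacylglycerols", list("Monoacylglycerols", 26)),
    .tplRows("Phosphatidylcholines",
      list("Saturated Phosphatidylcholines", 40),
      list("Unsaturated Phosphatidylcholines", 63)),
    .tplRows("Phosphatidylethanolamines",
      list("Saturated Phosphatidylethanolamines", 50),
      list("Unsaturated Phosphatidylethanolamines", 77)),
    .tplRows("Phosphatidylinositols", list("Phosphatidylinositols", 28)),
    .tplRows("Sphingolipids",
      list("Ceramides", 12),
      list("Dihydroceramides", 9),
      list("Hexosylceramides", 14),
      list("Lactosylceramides", 14),
      list("Sphingomyelins", 12)),
    .tplRows("Triacylglycerols",
      list("Saturated Triacylglycerols", 150),
      list("Monounsaturated Triacylglycerols", 180),
      list("Polyunsaturated Triacylglycerols", 188)))
}

#' Expand a pathway template into per-metabolite annotations
#'
#' @param template a template as returned by [defaultTemplate()].
#' @param idPrefix prefix for generated metabolite ids.
#' @return annotation data.frame with one row per metabolite.
#' @export
templateAnnotations <- function(template, idPrefix = NULL) {
  if (is.null(idPrefix))
    idPrefix <- ifelse(template$panel[1] == "lipid", "L", "G")
  idx <- rep(seq_len(nrow(template)), template$n_members)
  ann <- template[idx, c("sub_pathway", "super_pathway", "panel",
                         "imputation_class")]
  member <- sequence(template$n_members)
  ann$metabolite_id <- sprintf("%s%04d", idPrefix, seq_len(nrow(ann)))
  ann$name <- paste0(ann$sub_pathway, " ", member)
  ann$hmdb_id <- NA_character_
  rownames(ann) <- NULL
  ann[c("metabolite_id", "name", "super_pathway", "sub_pathway",
        "hmdb_id", "panel", "imputation_class")]
}
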