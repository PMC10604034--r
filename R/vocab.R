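# Controlled gene vocabulary and name normalization for vertebrate mitogenomes.

#' Controlled vocabulary of mitochondrial gene names
#'
#' The 13 protein-coding genes (PCGs), 22 tRNAs (with isoacceptor tags
#' trnL1/trnL2 and trnS1/trnS2), the two rRNAs and the control region, as a
#' tibble with the feature type of each name.
#'
#' @return A tibble with columns `gene` and `ftype`.
#' @export
#' @examples
#' mito_vocabulary()
mito_vocabulary <- function() {
  dplyr::bind_rows(
    tibble::tibble(gene = .pcg_names, ftype = "PCG"),
    tibble::tibble(gene = .trna_names, ftype = "tRNA"),
    tibble::tibble(gene = .rrna_names, ftype = "rRNA"),
    tibble::tibble(gene = "CR", ftype = "CR")
  )
}

.pcg_names <- c(
  "ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
  "COI", "COII", "COIII", "ATP6", "ATP8", "CYTB"
)

.trna_names <- c(
  "trnF", "trnV", "trnL1", "trnL2", "trnI", "trnQ", "trnM", "trnW", "trnA",
  "trnN", "trnC", "trnY", "trnS1", "trnS2", "trnD", "trnK", "trnG", "trnR",
  "trnH", "trnE", "trnT", "trnP"
)

.rrna_names <- c("rrnS", "rrnL")

# one-letter amino-acid code -> tRNA name stub
.aa1 <- c(
  F = "trnF", V = "trnV", I = "trnI", Q = "trnQ", M = "trnM", W = "trnW",
  A = "trnA", N = "trnN", C = "trnC", Y = "trnY", D = "trnD", K = "trnK",
  G = "trnG", R = "trnR", H = "trnH", E = "trnE", T = "trnT", P = "trnP"
)

.aa3 <- c(
  Phe = "trnF", Val = "trnV", Leu = "trnL", Ile = "trnI", Gln = "trnQ",
  Met = "trnM", Trp = "trnW", Ala = "trnA", Asn = "trnN", Cys = "trnC",
  Tyr = "trnY", Ser = "trnS", Asp = "trnD", Lys = "trnK", Gly = "trnG",
  Arg = "trnR", His = "trnH", Glu = "trnE", Thr = "trnT", Pro = "trnP"
)

#' Normalize a gene label to the controlled vocabulary
#'
#' Maps the synonym spellings seen in annotation tables (ND1/NAD1, COI/COX1,
#' Cytb/CYTB/COB, "12S rRNA"/rrnS, "tRNA-Phe"/trnF, "Control region"/D-loop)
#' onto the fixed vocabulary of [mito_vocabulary()]. The two leucine and two
#' serine tRNAs are disambiguated by their anticodon-column triplet
#' (TTA/TAA -> trnL2, CTA/TAG -> trnL1, TCA/TGA -> trnS2, AGC/GCT -> trnS1).
#'
#' @param name Character vector of gene labels.
#' @param anticodon Optional character vector of 3-mers (same length),
#'   used only to resolve Leu/Ser isoacceptors.
#' @return Character vector of canonical names; unrecognized labels are
#'   returned unchanged with a warning.
#' @export
#' @examples
#' normalize_gene_name(c("NAD1", "tRNA-Phe", "Control region"))
normalize_gene_name <- function(name, anticodon = NULL) {
  if (is.null(anticodon)) anticodon <- rep(NA_character_, length(name))
  stopifnot(length(anticodon) == length(name))
  out <- purrr::map2_chr(name, anticodon, .normalize_one)
  bad <- !(out %in% mito_vocabulary()$gene)
  if (any(bad)) {
    warning("unrecognized gene label(s) kept verbatim: ",
            paste(unique(out[bad]), collapse = ", "))
  }
  out
}

.normalize_one <- function(name, anticodon) {
  raw <- stringr::str_trim(name)
  x <- toupper(raw)
  x <- stringr::str_replace_all(x, "[ _]", "-")

  # control region
  if (stringr::str_detect(x, "^(CR|D-?LOOP|CONTROL-?REGION)$")) return("CR")
  # rRNAs
  if (stringr::str_detect(x, "12S|RRNS|SSU|^S-RRNA$|SMALL")) return("rrnS")
  if (stringr::str_detect(x, "16S|RRNL|LSU|^L-RRNA$|LARGE")) return("rrnL")

  # PCG synonyms
  pcg <- c(
    "^(ND|NAD|NADH)1$" = "ND1", "^(ND|NAD|NADH)2$" = "ND2",
    "^(ND|NAD|NADH)3$" = "ND3", "^(ND|NAD|NADH)4$" = "ND4",
    "^(ND|NAD|NADH)4L$" = "ND4L", "^(ND|NAD|NADH)5$" = "ND5",
    "^(ND|NAD|NADH)6$" = "ND6",
    "^(COI|COX1|CO1)$" = "COI", "^(COII|COX2|CO2)$" = "COII",
    "^(COIII|COX3|CO3)$" = "COIII",
    "^(ATP6|ATPASE6|ATPASE-6)$" = "ATP6", "^(ATP8|ATPASE8|ATPASE-8)$" = "ATP8",
    "^(CYTB|COB|CYT-B)$" = "CYTB"
  )
  for (pat in names(pcg)) if (stringr::str_detect(x, pat)) return(pcg[[pat]])

  # tRNAs: trnX / trnX1 / tRNA-Xxx
  m <- stringr::str_match(x, "^TRN([A-Z])([12])?$")
  if (!is.na(m[1, 1])) {
    stub <- .aa1[m[1, 2]]
    if (m[1, 2] %in% c("L", "S")) stub <- paste0("trn", m[1, 2])
    if (!is.na(m[1, 3])) return(paste0(stub, m[1, 3]))
    return(.resolve_isoacceptor(stub, anticodon))
  }
  m <- stringr::str_match(x, "^TRNA-([A-Z]{3})([12])?$")
  if (!is.na(m[1, 1])) {
    key <- stringr::str_to_title(m[1, 2])
    if (key %in% names(.aa3)) {
      stub <- .aa3[[key]]
      if (!is.na(m[1, 3])) return(paste0(stub, m[1, 3]))
      return(.resolve_isoacceptor(stub, anticodon))
    }
  }
  raw
}

# Leu/Ser carry isoacceptor tags; the anticodon-column triplet decides which.
.resolve_isoacceptor <- function(stub, anticodon) {
  if (!stub %in% c("trnL", "trnS")) return(stub)
  ac <- toupper(chartr("U", "T", ifelse(is.na(anticodon), "", anticodon)))
  if (stub == "trnL") {
    if (ac %in% c("TTA", "TAA")) return("trnL2")  # Leu(UUR)
    if (ac %in% c("CTA", "TAG")) return("trnL1")  # Leu(CUN)
  } else {
    if (ac %in% c("TCA", "TGA")) return("trnS2")  # Ser(UCN)
    if (ac %in% c("AGC", "GCT")) return("trnS1")  # Ser(AGY), DHU-less in many vertebrates
  }
  stub
}

#' Canonical vertebrate/teleost mitochondrial gene order
#'
#' The ancestral teleost arrangement of the 37 genes plus control region,
#' beginning at trnF, with the strand each feature occupies.
#'
#' @param include_cr Include the control region row (default TRUE).
#' @return A tibble with columns `gene`, `ftype`, `strand` in canonical order.
#' @export
#' @examples
#' canonical_teleost_order()
canonical_teleost_order <- function(include_cr = TRUE) {
  ord <- tibble::tribble(
    ~gene,   ~strand,
    "trnF",  "H", "rrnS",  "H", "trnV",  "H", "rrnL",  "H", "trnL2", "H",
    "ND1",   "H", "trnI",  "H", "trnQ",  "L", "trnM",  "H", "ND2",   "H",
    "trnW",  "H", "trnA",  "L", "trnN",  "L", "trnC",  "L", "trnY",  "L",
    "COI",   "H", "trnS2", "L", "trnD",  "H", "COII",  "H", "trnK",  "H",
    "ATP8",  "H", "ATP6",  "H", "COIII", "H", "trnG",  "H", "ND3",   "H",
    "trnR",  "H", "ND4L",  "H", "ND4",   "H", "trnH",  "H", "trnS1", "H",
    "trnL1", "H", "ND5",   "H", "ND6",   "L", "trnE",  "L", "CYTB",  "H",
    "trnT",  "H", "trnP",  "L", "CR",    "H"
  )
  ord <- dplyr::left_join(ord, mito_vocabulary(), by = "gene") |>
    dplyr::select("gene", "ftype", "strand")
  if (!include_cr) ord <- dplyr::filter(ord, .data$ftype != "CR")
  ord
}
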