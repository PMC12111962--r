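## Small in-code fixtures shared across test files.

## A minimal germline variant row; override fields as needed.
germline_row <- function(patient_id = "P001", gene = "TP53",
                         clinical_significance = "Pathogenic",
                         af_gnomad = 1e-4, af_1000g = NA_real_,
                         cadd_phred = 30, polyphen = "Probably damaging",
                         sift = "Deleterious", review_pass = TRUE) {
  data.frame(patient_id = patient_id, gene = gene,
             clinical_significance = clinical_significance,
             af_gnomad = af_gnomad, af_1000g = af_1000g,
             cadd_phred = cadd_phred, polyphen = polyphen, sift = sift,
             review_pass = review_pass, stringsAsFactors = FALSE)
}

## A somatic mutation row in the MAF-like dialect.
somatic_row <- function(patient_id = "P001", gene = "G0001", chrom = "1",
                        pos = 100, ref = "C", alt = "A", variant_class = "missense",
                        context3 = "ACA") {
  data.frame(patient_id = patient_id, gene = gene, chrom = chrom, pos = pos,
             ref = ref, alt = alt, variant_class = variant_class,
             context3 = context3, stringsAsFactors = FALSE)
}

## Random valid SNV records spread over the 96 channels, with roughly half
## emitted on the purine strand.
random_snvs <- function(n, patients = c("P001", "P002", "P003"), seed = 1) {
  set.seed(seed)
  channels <- sbs96_channels()
  ch <- sample(channels, n, replace = TRUE)
  ref <- substr(ch, 3, 3); alt <- substr(ch, 5, 5)
  cx <- paste0(substr(ch, 1, 1), ref, substr(ch, 7, 7))
  flip <- runif(n) < 0.5
  rc <- function(s) vapply(strsplit(chartr("ACGT", "TGCA", s), ""),
                           function(z) paste(rev(z), collapse = ""),
                           character(1))
  ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  cx[flip] <- rc(cx[flip])
  data.frame(patient_id = sample(patients, n, replace = TRUE),
             gene = "G0001", chrom = "1", pos = seq_len(n), ref = ref,
             alt = alt, variant_class = "missense", context3 = cx,
             channel = ch, stringsAsFactors = FALSE)
}

## Reverse-complement every SNV record (the other strand representation).
revcomp_records <- function(snvs) {
  rc <- function(s) vapply(strsplit(chartr("ACGT", "TGCA", s), ""),
                           function(z) paste(rev(z), collapse = ""),
                           character(1))
  snvs$ref <- chartr("ACGT", "TGCA", snvs$ref)
  snvs$alt <- chartr("ACGT", "TGCA", snvs$alt)
  snvs$context3 <- rc(snvs$context3)
  snvs
}
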