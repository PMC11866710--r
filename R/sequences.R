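# Canonical alphabets.  Orders are fixed so that learned-weight heatmaps and
# one-hot encodings are reproducible across runs: nucleotides A,C,G,T; amino
# acids alphabetical by one-letter code; codons in lexicographic order.
NT_ALPHABET <- c("A", "C", "G", "T")
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
CODONS <- as.vector(t(outer(
  as.vector(t(outer(NT_ALPHABET, NT_ALPHABET, paste0))), NT_ALPHABET, paste0)))

#' Per-gene sequence record
#'
#' @param gene_id identifier.
#' @param utr5,cds,utr3 nucleotide strings (A/C/G/T/N); UTRs may be empty,
#'   the CDS must be at least 6 nt.
#' @param protein amino-acid string; derived by translation of the CDS when
#'   not supplied.
#' @return Object of class `gene_seq_record`.
#' @export
gene_seq_record <- function(gene_id, utr5 = "", cds, utr3 = "", protein = NULL) {
  if (nchar(cds) < 6) stop("CDS for gene ", gene_id, " is shorter than 6 nt")
  if (is.null(protein)) protein <- translate_cds(cds, warn = FALSE)
  structure(list(gene_id = gene_id, utr5 = toupper(utr5), cds = toupper(cds),
                 utr3 = toupper(utr3), protein = toupper(protein)),
            class = "gene_seq_record")
}

#' One-hot encode a sequence with zero padding
#'
#' Column i is the indicator of the i-th symbol; columns past the sequence
#' end, and columns for symbols outside the alphabet (e.g. `N`), are all
#' zero, so every column sums to 1 or 0.
#'
#' @param seq character string.
#' @param alphabet ordered symbol vector (rows of the output).
#' @param pad_to output width; sequences longer than `pad_to` are truncated
#'   at the 3' end (C-terminus for proteins).
#' @return `length(alphabet)` x `pad_to` numeric matrix.
#' @export
one_hot_encode <- function(seq, alphabet = NT_ALPHABET, pad_to = nchar(seq)) {
  if (length(alphabet) == 0) stop("alphabet must be non-empty")
  m <- matrix(0, nrow = length(alphabet), ncol = pad_to,
              dimnames = list(alphabet, NULL))
  n <- min(nchar(seq), pad_to)
  if (n > 0) {
    chars <- strsplit(substr(seq, 1, n), "")[[1]]
    idx <- match(chars, alphabet)
    ok <- !is.na(idx)
    m[cbind(idx[ok], seq_len(n)[ok])] <- 1
  }
  m
}

#' Codon counts of a coding sequence at a given frame shift
#'
#' Counts non-overlapping triplets starting at offset `shift` (0, 1 or 2
#' nucleotides); a trailing partial triplet and triplets containing non-ACGT
#' symbols are discarded.
#'
#' @param cds nucleotide string.
#' @param shift reading-frame shift in nucleotides.
#' @return Named 64-vector over [CODONS].
#' @export
codon_counts <- function(cds, shift = 0) {
  stopifnot(shift %in% 0:2)
  if (nchar(cds) < shift + 3)
    stop("CDS shorter than shift + 3")
  n <- nchar(cds) - shift
  n_cod <- n %/% 3
  starts <- shift + 1 + 3 * (seq_len(n_cod) - 1)
  triplets <- substring(cds, starts, starts + 2)
  counts <- table(factor(triplets, levels = CODONS))
  stats::setNames(as.integer(counts), CODONS)
}

#' Nucleotide counts
#'
#' @param seq nucleotide string; symbols outside A/C/G/T are ignored.
#' @return Named 4-vector.
#' @export
nucleotide_counts <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  counts <- table(factor(chars, levels = NT_ALPHABET))
  stats::setNames(as.integer(counts), NT_ALPHABET)
}

#' Amino-acid counts
#'
#' @param protein amino-acid string; symbols outside the 20 canonical
#'   one-letter codes are ignored.
#' @return Named 20-vector.
#' @export
amino_acid_counts <- function(protein) {
  chars <- strsplit(protein, "")[[1]]
  counts <- table(factor(chars, levels = AA_ALPHABET))
  stats::setNames(as.integer(counts), AA_ALPHABET)
}

#' Translate a coding sequence (standard genetic code)
#'
#' Translation stops at the first stop codon; the terminal stop is not
#' emitted.  An internal stop (before the final codon) triggers a warning and
#' the truncated protein is returned.  Codons containing ambiguous
#' nucleotides translate to `X`.
#'
#' @param cds nucleotide string with length divisible by 3.
#' @param warn emit the internal-stop warning (default TRUE).
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds, warn = TRUE) {
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  code <- Biostrings::GENETIC_CODE
  starts <- seq(1, nchar(cds), by = 3)
  triplets <- substring(cds, starts, starts + 2)
  aa <- code[triplets]
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0) {
    first <- stop_at[1]
    if (warn && first < length(aa))
      warning("internal stop codon at codon ", first, "; protein truncated")
    aa <- aa[seq_len(first - 1)]
  }
  paste(aa, collapse = "")
}

#' Start-/stop-codon context window as a flattened one-hot
#'
#' For `anchor = "start"` the window covers the last `w_up` nucleotides of
#' the 5'UTR, the start codon, and the following `w_down` nucleotides of the
#' CDS; for `anchor = "stop"` it covers the `w_up` CDS nucleotides before the
#' stop codon, the stop codon, and the first `w_down` nucleotides of the
#' 3'UTR.  Positions not covered by the available sequence are all-zero
#' columns.  The result is the row-major flattening of the
#' 4 x (w_up + 3 + w_down) one-hot matrix.
#'
#' @param record a [gene_seq_record].
#' @param anchor `"start"` or `"stop"`.
#' @param w_up,w_down window extent up/downstream of the anchor codon.
#' @return Numeric vector of length `4 * (w_up + 3 + w_down)`.
#' @export
codon_context <- function(record, anchor = c("start", "stop"),
                          w_up = 6, w_down = 9) {
  anchor <- match.arg(anchor)
  cds <- record$cds
  if (nchar(cds) < 6) stop("CDS shorter than 6 nt for gene ", record$gene_id)
  w <- w_up + 3 + w_down
  if (anchor == "start") {
    up <- if (nchar(record$utr5) > 0)
      substr(record$utr5, max(1, nchar(record$utr5) - w_up + 1),
             nchar(record$utr5)) else ""
    mid_down <- substr(cds, 1, 3 + w_down)
    # left-pad so the anchor codon always sits at columns w_up+1 .. w_up+3
    left_pad <- w_up - nchar(up)
    seqstr <- paste0(up, mid_down)
  } else {
    body <- substr(cds, 1, nchar(cds) - 3)
    stopc <- substr(cds, nchar(cds) - 2, nchar(cds))
    up <- substr(body, max(1, nchar(body) - w_up + 1), nchar(body))
    down <- substr(record$utr3, 1, w_down)
    left_pad <- w_up - nchar(up)
    seqstr <- paste0(up, stopc, down)
  }
  m <- matrix(0, 4, w, dimnames = list(NT_ALPHABET, NULL))
  inner <- one_hot_encode(seqstr, NT_ALPHABET, pad_to = w - left_pad)
  if (ncol(inner) > 0) m[, (left_pad + 1):w] <- inner
  as.vector(t(m))
}

# ---- FASTA I/O -------------------------------------------------------------

#' Read per-gene sequences from FASTA files
#'
#' Each file is keyed by gene ID (first whitespace-delimited token of the
#' header).  Genes present in `gene_ids` but missing from a file get the
#' empty string for that region; the protein is derived by translation when
#' no protein FASTA is given.
#'
#' @param cds_fasta path to the CDS FASTA (required).
#' @param utr5_fasta,utr3_fasta,protein_fasta optional FASTA paths.
#' @param gene_ids genes to load; defaults to the IDs in the CDS file.
#' @return Named list of [gene_seq_record]s.
#' @export
read_gene_sequences <- function(cds_fasta, utr5_fasta = NULL, utr3_fasta = NULL,
                                protein_fasta = NULL, gene_ids = NULL) {
  read_map <- function(path, reader) {
    if (is.null(path)) return(character(0))
    s <- reader(path)
    v <- as.character(s)
    names(v) <- vapply(strsplit(names(s), "\\s+"), `[[`, "", 1)
    v
  }
  cds <- read_map(cds_fasta, Biostrings::readDNAStringSet)
  utr5 <- read_map(utr5_fasta, Biostrings::readDNAStringSet)
  utr3 <- read_map(utr3_fasta, Biostrings::readDNAStringSet)
  pep <- read_map(protein_fasta, Biostrings::readAAStringSet)
  if (is.null(gene_ids)) gene_ids <- names(cds)
  get <- function(map, id) if (id %in% names(map)) map[[id]] else ""
  recs <- lapply(gene_ids, function(id) {
    if (!id %in% names(cds)) stop("gene ", id, " missing from CDS FASTA")
    gene_seq_record(id, utr5 = get(utr5, id), cds = cds[[id]],
                    utr3 = get(utr3, id),
                    protein = if (id %in% names(pep)) pep[[id]] else NULL)
  })
  stats::setNames(recs, gene_ids)
}

#' Write gene sequences to FASTA files
#'
#' @param records named list of [gene_seq_record]s.
#' @param dir output directory; files `utr5.fa`, `cds.fa`, `utr3.fa`,
#'   `pep.fa` are created.
#' @export
write_gene_sequences <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(records, `[[`, "", "gene_id")
  wr <- function(field, file, cls) {
    v <- vapply(records, `[[`, "", field)
    s <- do.call(cls, list(stats::setNames(v, ids)))
    Biostrings::writeXStringSet(s, file.path(dir, file))
  }
  wr("utr5", "utr5.fa", Biostrings::DNAStringSet)
  wr("cds", "cds.fa", Biostrings::DNAStringSet)
  wr("utr3", "utr3.fa", Biostrings::DNAStringSet)
  wr("protein", "pep.fa", Biostrings::AAStringSet)
  invisible(dir)
}

# ---- Feature bundle --------------------------------------------------------

#' Encode a gene set into model-ready feature matrices
#'
#' Builds the eight input features used by the model: codon counts at frame
#' shifts 0/1/2, nucleotide counts per region, amino-acid counts,
#' start-/stop-codon context one-hots, and padded one-hot matrices for the
#' 5'UTR, CDS, 3'UTR and protein.  Count features are kept as raw integers;
#' the model applies its log2(1 + x) transform internally.
#'
#' @param records named list of [gene_seq_record]s.
#' @param w_up,w_down context-window extents (see [codon_context()]).
#' @param pad_to named list overriding the pad length per sequence feature
#'   (`utr5`, `cds`, `utr3`, `pep`); default is the maximum observed length.
#' @return Object of class `ptr_features`: a list of genes x dims matrices
#'   (`counts`) and one-hot matrix lists (`onehot`).
#' @export
encode_features <- function(records, w_up = 6, w_down = 9, pad_to = list()) {
  ids <- unname(vapply(records, `[[`, "", "gene_id"))
  rows <- function(f) {
    m <- t(vapply(records, f, numeric(length(f(records[[1]])))))
    rownames(m) <- ids
    m
  }
  counts <- list(
    codon_f0 = rows(function(r) codon_counts(r$cds, 0)),
    codon_f1 = rows(function(r) codon_counts(r$cds, 1)),
    codon_f2 = rows(function(r) codon_counts(r$cds, 2)),
    nt_utr5  = rows(function(r) nucleotide_counts(r$utr5)),
    nt_cds   = rows(function(r) nucleotide_counts(r$cds)),
    nt_utr3  = rows(function(r) nucleotide_counts(r$utr3)),
    aa       = rows(function(r) amino_acid_counts(r$protein)),
    start_context = rows(function(r) codon_context(r, "start", w_up, w_down)),
    stop_context  = rows(function(r) codon_context(r, "stop", w_up, w_down))
  )
  pad <- function(field, default_field) {
    lens <- vapply(records, function(r) nchar(r[[default_field]]), 0L)
    if (!is.null(pad_to[[field]])) pad_to[[field]] else max(lens, 1L)
  }
  p5 <- pad("utr5", "utr5"); pc <- pad("cds", "cds")
  p3 <- pad("utr3", "utr3"); pp <- pad("pep", "protein")
  onehot <- list(
    utr5 = lapply(records, function(r) one_hot_encode(r$utr5, NT_ALPHABET, p5)),
    cds  = lapply(records, function(r) one_hot_encode(r$cds, NT_ALPHABET, pc)),
    utr3 = lapply(records, function(r) one_hot_encode(r$utr3, NT_ALPHABET, p3)),
    pep  = lapply(records, function(r) one_hot_encode(r$protein, AA_ALPHABET, pp))
  )
  structure(list(gene_ids = ids, counts = counts, onehot = onehot,
                 w_up = w_up, w_down = w_down),
            class = "ptr_features")
}
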