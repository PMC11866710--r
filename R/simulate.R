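# Synthetic genomes and matched expression datasets with planted ground
# truth, so the whole pipeline is testable without any external download.
# Per gene the generator samples UTR/CDS sequences (CDS as a clean ORF),
# optionally implants motifs, derives a true gradient a from the planted
# sequence effects, and emits log2 iBAQ = a * log2 TPM + b (+ delta terms)
# with Gaussian noise and detection-threshold-like missingness.

#' Generative specification for synthetic PTR data
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package: 400 genes x 30 tissues, CDS 300-900 nt, UTRs 50-300 nt, log2 TPM
#' ~ Normal(3, 2), observation noise sd 0.3, 10% threshold-biased
#' missingness, baseline gradient 0.5 with a single causal codon (GAA,
#' +0.05 per count) and a shared offset of 14 (typical log2 iBAQ scale).
#'
#' @param n_genes,n_tissues dataset size.
#' @param utr5_len,cds_len,utr3_len length ranges (CDS in nt, rounded to a
#'   multiple of 3).
#' @param planted_motifs list of `list(region=, kmer=, effect=, prob=)`;
#'   each gene carries the motif with probability `prob`, implanted at a
#'   uniform position, adding `effect` to its true gradient.
#' @param codon_effects named numeric vector of per-count effects on the
#'   gradient (names are codons).
#' @param context_regulators list of `list(gene=, effect=, targets=)`:
#'   regulator gene index, delta coefficient, and target indices (default:
#'   every other gene).
#' @param tpm_log2_mean,tpm_log2_sd log2 TPM distribution.
#' @param noise_sd sd of the Gaussian noise on log2 iBAQ.
#' @param missing_rate base missingness probability (scaled by a logistic
#'   detection-threshold term, so low-abundance cells drop out more often).
#' @param a_base baseline gradient.
#' @param b_mean,b_sd per-gene offset distribution.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return List of class `generative_spec`.
#' @export
generative_spec <- function(n_genes = 400, n_tissues = 30,
                            utr5_len = c(50, 300), cds_len = c(300, 900),
                            utr3_len = c(50, 300),
                            planted_motifs = list(),
                            codon_effects = c(GAA = 0.05),
                            context_regulators = list(),
                            tpm_log2_mean = 3, tpm_log2_sd = 2,
                            noise_sd = 0.3, missing_rate = 0.1,
                            a_base = 0.5, b_mean = 14, b_sd = 0,
                            seed = 1) {
  spec <- as.list(environment())
  stopifnot(missing_rate >= 0, missing_rate <= 1, noise_sd >= 0,
            all(cds_len > 0))
  for (m in spec$planted_motifs) {
    min_len <- switch(m$region, utr5 = utr5_len[1], utr3 = utr3_len[1],
                      cds = cds_len[1], stop("unknown motif region: ", m$region))
    if (nchar(m$kmer) > min_len)
      stop("planted motif longer than minimum ", m$region, " length")
  }
  class(spec) <- "generative_spec"
  spec
}

#' Motif-recovery scenario
#'
#' One 8-mer planted in the 5'UTR (G-box-like `GCACGTGG`, carried by half
#' the genes) adds +0.4 to the gradient; no codon effects, so the motif is
#' the only sequence signal.
#'
#' @param ... overrides passed to [generative_spec()].
#' @export
spec_motif_recovery <- function(...) {
  generative_spec(planted_motifs = list(list(region = "utr5",
                                             kmer = "GCACGTGG",
                                             effect = 0.4, prob = 0.5)),
                  codon_effects = numeric(0), ...)
}

#' Context-regulator scenario
#'
#' Gene 1's transcript level enters every other gene's protein level with a
#' planted delta coefficient (default +0.5), on top of the default codon
#' effect.
#'
#' @param delta planted coefficient.
#' @param ... overrides passed to [generative_spec()].
#' @export
spec_context_regulator <- function(delta = 0.5, ...) {
  generative_spec(context_regulators = list(list(gene = 1, effect = delta)),
                  ...)
}

#' Master-regulator screen scenario
#'
#' 200 genes, gene 1 drives the proteins of 50 target genes with delta = 1;
#' used to validate the cross-correlation screen.
#'
#' @param n_genes,n_targets,delta scenario sizes and effect.
#' @param ... overrides passed to [generative_spec()].
#' @export
spec_master_regulator <- function(n_genes = 200, n_targets = 50, delta = 1,
                                  ...) {
  generative_spec(n_genes = n_genes,
                  context_regulators = list(list(gene = 1, effect = delta,
                                                 targets = 2:(n_targets + 1))),
                  ...)
}

sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

stop_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code == "*"]
}

random_nt <- function(n) paste(sample(NT_ALPHABET, n, replace = TRUE),
                               collapse = "")

#' Generate a synthetic dataset with planted ground truth
#'
#' @param spec a [generative_spec()].
#' @return List of class `ptr_simulation` with `records` (named list of
#'   [gene_seq_record]s), `dataset` (a [ptr_dataset]) and `truth`
#'   (data.frame of per-gene true `a`, `b`, motif carrier flags; plus the
#'   regulator list and the noise-free matrices).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "generative_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  ids <- sprintf("gene%04d", seq_len(n))
  sense <- sense_codons()
  stops <- stop_codons()
  records <- vector("list", n)
  a_true <- rep(spec$a_base, n)
  motif_carrier <- matrix(FALSE, n, length(spec$planted_motifs))
  for (g in seq_len(n)) {
    u5 <- random_nt(sample(spec$utr5_len[1]:spec$utr5_len[2], 1))
    u3 <- random_nt(sample(spec$utr3_len[1]:spec$utr3_len[2], 1))
    n_cod <- sample((spec$cds_len[1] %/% 3):(spec$cds_len[2] %/% 3), 1)
    body <- paste(sample(sense, max(n_cod - 2, 1), replace = TRUE),
                  collapse = "")
    cds <- paste0("ATG", body, sample(stops, 1))
    for (k in seq_along(spec$planted_motifs)) {
      m <- spec$planted_motifs[[k]]
      if (stats::runif(1) < (m$prob %||% 0.5)) {
        motif_carrier[g, k] <- TRUE
        km <- m$kmer
        tgt <- switch(m$region, utr5 = u5, utr3 = u3, cds = cds)
        pos <- sample(nchar(tgt) - nchar(km) + 1, 1)
        substr(tgt, pos, pos + nchar(km) - 1) <- km
        if (m$region == "utr5") u5 <- tgt
        else if (m$region == "utr3") u3 <- tgt
        else cds <- tgt
        a_true[g] <- a_true[g] + m$effect
      }
    }
    if (length(spec$codon_effects) > 0) {
      cc <- codon_counts(cds, 0)
      a_true[g] <- a_true[g] +
        sum(spec$codon_effects * cc[names(spec$codon_effects)])
    }
    records[[g]] <- gene_seq_record(ids[g], utr5 = u5, cds = cds, utr3 = u3)
  }
  names(records) <- ids
  b_true <- stats::rnorm(n, spec$b_mean, spec$b_sd)
  tis <- sprintf("tissue%02d", seq_len(spec$n_tissues))
  log2_tpm <- matrix(stats::rnorm(n * spec$n_tissues, spec$tpm_log2_mean,
                                  spec$tpm_log2_sd),
                     n, spec$n_tissues, dimnames = list(ids, tis))
  log2_ibaq_clean <- log2_tpm * a_true + b_true
  for (reg in spec$context_regulators) {
    targets <- reg$targets %||% setdiff(seq_len(n), reg$gene)
    log2_ibaq_clean[targets, ] <- log2_ibaq_clean[targets, ] +
      matrix(reg$effect * log2_tpm[reg$gene, ], length(targets),
             spec$n_tissues, byrow = TRUE)
  }
  log2_ibaq <- log2_ibaq_clean +
    matrix(stats::rnorm(n * spec$n_tissues, 0, spec$noise_sd),
           n, spec$n_tissues)
  # threshold-biased missingness: cells near/below the detection limit drop
  # out more often (logistic weight, normalized so the overall masking
  # fraction equals missing_rate), mimicking truncation at low abundance
  drop_mask <- function(m, threshold) {
    w <- stats::plogis(-(m - threshold))
    p <- pmin(spec$missing_rate * w / mean(w), 1)
    matrix(stats::runif(length(m)) < p, nrow(m))
  }
  tpm_miss <- drop_mask(log2_tpm, threshold = 0)
  ibaq_miss <- drop_mask(log2_ibaq, threshold = log2(5000))
  log2_tpm_obs <- log2_tpm; log2_tpm_obs[tpm_miss] <- NA
  log2_ibaq_obs <- log2_ibaq; log2_ibaq_obs[ibaq_miss] <- NA
  truth <- data.frame(gene_id = ids, a = a_true, b = b_true,
                      stringsAsFactors = FALSE)
  if (ncol(motif_carrier) > 0)
    truth <- cbind(truth, stats::setNames(
      as.data.frame(motif_carrier),
      paste0("motif", seq_len(ncol(motif_carrier)))))
  structure(list(
    records = records,
    dataset = ptr_dataset(log2_tpm_obs, log2_ibaq_obs, ids, tis),
    truth = list(genes = truth, regulators = spec$context_regulators,
                 log2_tpm_clean = log2_tpm, log2_ibaq_clean = log2_ibaq_clean),
    spec = spec
  ), class = "ptr_simulation")
}

#' Write a simulation to disk as plain-text fixtures
#'
#' FASTA files for the four sequence regions, raw-scale expression TSVs
#' (2^log2 values, readable by the preprocessing loaders, empty cell =
#' missing) and a ground-truth JSON.
#'
#' @param sim a `ptr_simulation`.
#' @param dir output directory.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_sequences(sim$records, dir)
  write_expression_tsv(2^sim$dataset$log2_tpm, file.path(dir, "tpm.tsv"))
  write_expression_tsv(2^sim$dataset$log2_ibaq, file.path(dir, "ibaq.tsv"))
  truth <- list(genes = sim$truth$genes, regulators = sim$truth$regulators,
                spec = sim$spec[setdiff(names(sim$spec),
                                        c("planted_motifs",
                                          "context_regulators"))],
                planted_motifs = sim$spec$planted_motifs)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return List with `records`, `dataset` (thresholded and log2-transformed
#'   via [preprocess_expression()]) and `truth`.
#' @export
read_fixture <- function(dir) {
  records <- read_gene_sequences(
    cds_fasta = file.path(dir, "cds.fa"),
    utr5_fasta = file.path(dir, "utr5.fa"),
    utr3_fasta = file.path(dir, "utr3.fa"),
    protein_fasta = file.path(dir, "pep.fa"))
  tpm <- read_expression_tsv(file.path(dir, "tpm.tsv"))
  ibaq <- read_expression_tsv(file.path(dir, "ibaq.tsv"))
  dataset <- preprocess_expression(tpm, ibaq)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(records = records, dataset = dataset, truth = truth)
}
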