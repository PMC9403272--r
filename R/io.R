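## Readers/writers for the interchange formats: TSV tables (tab-separated,
## UTF-8, mandatory header, "." for missing), FASTA, Newick.

NA_SENTINEL <- "."

writeTsvFile <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df))
    if (is.character(df[[j]])) df[[j]][is.na(df[[j]]) | df[[j]] == ""] <-
        NA_SENTINEL
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = NA_SENTINEL,
                     fileEncoding = "UTF-8")
  invisible(path)
}

readTsvFile <- function(path, required = character(), colClasses = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, na.strings = NA_SENTINEL,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          colClasses = colClasses)
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  df
}

#' Read and write genome functional-role annotations
#'
#' Wide format: `genome_id`, the seven taxonomy ranks, then one 0/1 column
#' per functional role. Long format (auto-detected on read): columns
#' `genome_id`, `role_id`, `present`, with taxonomy all `"undefined"`.
#'
#' @param path TSV file path.
#' @return [readRoleAnnotations()]: a [FunctionalRoleMatrix-class];
#'   [writeRoleAnnotations()]: the path, invisibly.
#' @export
readRoleAnnotations <- function(path) {
  df <- readTsvFile(path, required = "genome_id")
  if (all(c("role_id", "present") %in% colnames(df))) {
    ids <- unique(df$genome_id)
    roles <- sort(unique(df$role_id))
    m <- matrix(FALSE, length(ids), length(roles),
                dimnames = list(ids, roles))
    keep <- df$present %in% c(1, "1", TRUE)
    m[cbind(match(df$genome_id[keep], ids),
            match(df$role_id[keep], roles))] <- TRUE
    return(FunctionalRoleMatrix(m, exampleTaxonomy(ids)))
  }
  if (!all(taxonomyRanks() %in% colnames(df)))
    stop(path, ": wide annotation table needs the seven taxonomy columns")
  if (anyDuplicated(df$genome_id)) {
    bad <- df$genome_id[duplicated(df$genome_id)][1L]
    stop(sprintf("%s: duplicate genome_id '%s' (line %d)", path, bad,
                 which(df$genome_id == bad)[2L] + 1L))
  }
  roleCols <- setdiff(colnames(df), c("genome_id", taxonomyRanks()))
  m <- as.matrix(df[, roleCols, drop = FALSE])
  rownames(m) <- df$genome_id
  tx <- df[, taxonomyRanks(), drop = FALSE]
  rownames(tx) <- df$genome_id
  FunctionalRoleMatrix(m == 1, tx)
}

#' @param frm a [FunctionalRoleMatrix-class].
#' @rdname readRoleAnnotations
#' @export
writeRoleAnnotations <- function(frm, path) {
  df <- data.frame(genome_id = genomeIds(frm), taxonomy(frm),
                   roleMatrix(frm) * 1L, check.names = FALSE)
  writeTsvFile(df, path)
}

#' Read and write a Binary Phenotype Matrix
#'
#' TSV with `genome_id`, the seven taxonomy ranks, one 0/1 column per
#' phenotype, and one variant-combination column per phenotype (named
#' `variants.<phenotype>`, `"."` when no variant is complete). Writer and
#' reader round-trip losslessly.
#'
#' @param path TSV file path.
#' @return [readBpm()]: a [BinaryPhenotypeMatrix-class]; [writeBpm()]: the
#'   path, invisibly.
#' @export
readBpm <- function(path) {
  vcols <- paste0("variants.", scfaPhenotypes())
  df <- readTsvFile(path, required = c("genome_id", taxonomyRanks(),
                                       scfaPhenotypes(), vcols),
                    colClasses = stats::setNames(
                      rep("character", length(vcols) + 8L),
                      c("genome_id", taxonomyRanks(), vcols)))
  if (anyDuplicated(df$genome_id))
    stop(path, ": duplicate genome_id")
  ph <- as.matrix(df[, scfaPhenotypes(), drop = FALSE])
  storage.mode(ph) <- "integer"
  rownames(ph) <- df$genome_id
  v <- as.matrix(df[, vcols, drop = FALSE])
  v[is.na(v)] <- ""
  dimnames(v) <- dimnames(ph)
  tx <- df[, taxonomyRanks(), drop = FALSE]
  rownames(tx) <- df$genome_id
  new("BinaryPhenotypeMatrix", phenotypes = ph, variants = v, taxonomy = tx)
}

#' @param bpm a [BinaryPhenotypeMatrix-class].
#' @rdname readBpm
#' @export
writeBpm <- function(bpm, path) {
  v <- variantCalls(bpm)
  colnames(v) <- paste0("variants.", colnames(v))
  df <- data.frame(genome_id = genomeIds(bpm), taxonomy(bpm),
                   phenotypeMatrix(bpm), v, check.names = FALSE)
  writeTsvFile(df, path)
}

#' Read and write sample-by-feature abundance tables
#'
#' TSV with `sample_id` in the first column and one column per ASV or
#' taxon.
#'
#' @param path TSV file path.
#' @return [readAbundanceTable()]: numeric matrix samples x features;
#'   [writeAbundanceTable()]: the path, invisibly.
#' @export
readAbundanceTable <- function(path) {
  df <- readTsvFile(path, required = "sample_id")
  if (anyDuplicated(df$sample_id)) stop(path, ": duplicate sample_id")
  m <- as.matrix(df[, setdiff(colnames(df), "sample_id"), drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  m
}

#' @param abundance samples x features numeric matrix.
#' @rdname readAbundanceTable
#' @export
writeAbundanceTable <- function(abundance, path) {
  writeTsvFile(data.frame(sample_id = rownames(abundance), abundance,
                          check.names = FALSE), path)
}

#' Read and write feature-by-sample count tables
#'
#' TSV with `role_id` in the first column and one integer column per
#' sample.
#'
#' @param path TSV file path.
#' @return [readCountTable()]: integer matrix roles x samples;
#'   [writeCountTable()]: the path, invisibly.
#' @export
readCountTable <- function(path) {
  df <- readTsvFile(path, required = "role_id")
  if (anyDuplicated(df$role_id)) stop(path, ": duplicate role_id")
  m <- as.matrix(df[, setdiff(colnames(df), "role_id"), drop = FALSE])
  rownames(m) <- df$role_id
  if (any(m < 0, na.rm = TRUE)) stop(path, ": negative count")
  m
}

#' @param counts roles x samples count matrix.
#' @rdname readCountTable
#' @export
writeCountTable <- function(counts, path) {
  writeTsvFile(data.frame(role_id = rownames(counts), counts,
                          check.names = FALSE), path)
}

#' Read 16S copy numbers
#'
#' TSV with columns `asv_id` (or `taxon`) and `copy_number`.
#'
#' @param path TSV file path.
#' @return Named numeric vector of copy numbers.
#' @export
readCopyNumbers <- function(path) {
  df <- readTsvFile(path, required = "copy_number")
  key <- if ("asv_id" %in% colnames(df)) "asv_id" else "taxon"
  if (!key %in% colnames(df))
    stop(path, ": needs an asv_id or taxon column")
  if (anyDuplicated(df[[key]])) stop(path, ": duplicate ids")
  stats::setNames(as.numeric(df$copy_number), df[[key]])
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers over Biostrings with duplicate-id checking.
#'
#' @param path FASTA file path.
#' @return [readFastaSequences()]: a named
#'   [Biostrings::DNAStringSet]; [writeFastaSequences()]: the path,
#'   invisibly.
#' @export
readFastaSequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop(path, ": duplicate sequence id '",
         names(x)[duplicated(names(x))][1L], "'")
  x
}

#' @param seqs named [Biostrings::DNAStringSet] or character vector.
#' @rdname readFastaSequences
#' @export
writeFastaSequences <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a rooted Newick tree
#'
#' Reads with ape and validates: branch lengths present and non-negative,
#' unique leaf names.
#'
#' @param path Newick file path.
#' @return A `phylo` tree.
#' @export
readNewickTree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  checkTree(ape::read.tree(path))
}

#' Write a CPI profile as a long TSV
#'
#' Columns: `sample_id`, `phenotype`, `cpi`, `sigma`, `variance`,
#' `coverage`, `retained`.
#'
#' @param profile a [CpiProfile-class].
#' @param path TSV file path.
#' @return The path, invisibly.
#' @export
writeCpiProfile <- function(profile, path) {
  cm <- cpi(profile)
  long <- do.call(rbind, lapply(colnames(cm), function(ph) data.frame(
    sample_id = rownames(cm), phenotype = ph, cpi = cm[, ph],
    sigma = cpiError(profile)[, ph], variance = cpiVariance(profile)[, ph],
    coverage = sampleCoverage(profile), retained = isRetained(profile),
    stringsAsFactors = FALSE)))
  writeTsvFile(long, path)
}
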