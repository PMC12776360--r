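#' Construct an embedding matrix object
#'
#' An `dti_embeddings` object holds an ID-indexed real matrix of entity
#' encodings: one row per protein or drug, one column per embedding
#' dimension. These are the inputs the similarity graphs and the DCGAT stack
#' consume; in applications they typically come from a protein language model
#' (e.g. 1280-dimensional ESM-2 encodings of amino-acid sequences) and a
#' chemical language model over SMILES strings, but any real-valued encoding
#' is accepted.
#'
#' @param ids character vector of unique entity identifiers (opaque strings;
#'   no case folding or normalisation is applied).
#' @param values numeric matrix with `length(ids)` rows; all entries finite.
#' @param modality `"protein"` or `"drug"`.
#' @return An object of class `dti_embeddings` with fields `ids`, `values`
#'   (rownames set to `ids`) and `modality`.
#' @export
dti_embeddings <- function(ids, values, modality = c("protein", "drug")) {
  modality <- match.arg(modality)
  ids <- as.character(ids)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stop_if(nrow(values) != length(ids),
          "row count (", nrow(values), ") does not match id count (",
          length(ids), ")")
  dup <- ids[duplicated(ids)]
  stop_if(length(dup) > 0, "duplicate id(s): ", paste(unique(dup), collapse = ", "))
  stop_if(any(!is.finite(values)), "non-finite entries in embedding matrix")
  rownames(values) <- ids
  structure(list(ids = ids, values = values, modality = modality),
            class = "dti_embeddings")
}

#' @export
print.dti_embeddings <- function(x, ...) {
  cat(sprintf("<dti_embeddings> %s: %d entities x %d dims\n",
              x$modality, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read an embedding matrix from a delimited file
#'
#' Canonical format is tab-delimited text with a header row: first column the
#' entity ID, remaining columns numeric embedding values.
#'
#' @param path file path.
#' @param modality `"protein"` or `"drug"`.
#' @param sep field separator (default tab).
#' @return A [dti_embeddings] object; row order preserved from the file.
#' @export
read_embeddings <- function(path, modality = c("protein", "drug"), sep = "\t") {
  modality <- match.arg(modality)
  stop_if(!file.exists(path), "file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  stop_if(ncol(df) < 2, "embedding file needs an ID column and >=1 value column")
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  stop_if(length(dup) > 0, "duplicate id(s) in ", path, ": ",
          paste(unique(dup), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric value at row ", bad[1L], ", column ", bad[2L] + 1L,
         " of ", path, call. = FALSE)
  }
  dti_embeddings(ids, num, modality)
}

#' Write an embedding matrix to a tab-delimited file
#'
#' @param emb a [dti_embeddings] object.
#' @param path output path.
#' @param digits significant digits kept in the text representation.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path, digits = 17) {
  stopifnot(inherits(emb, "dti_embeddings"))
  d <- ncol(emb$values)
  header <- paste(c("id", paste0("v", seq_len(d))), collapse = "\t")
  rows <- vapply(seq_along(emb$ids), function(i) {
    paste(c(emb$ids[i], format(emb$values[i, ], digits = digits,
                               scientific = TRUE, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Construct an interaction table
#'
#' Holds (drug_id, protein_id, label) triples with binary labels; each pair
#' appears at most once.
#'
#' @param drug_id,protein_id character vectors.
#' @param label integer vector in \{0, 1\}.
#' @param provenance free-text source tag.
#' @return A `data.frame` of class `dti_interactions` with columns
#'   `drug_id`, `protein_id`, `label`.
#' @export
dti_interactions <- function(drug_id, protein_id, label, provenance = "") {
  drug_id <- as.character(drug_id); protein_id <- as.character(protein_id)
  stop_if(length(drug_id) != length(protein_id) ||
            length(drug_id) != length(label), "column lengths differ")
  stop_if(!all(label %in% c(0, 1, "0", "1")),
          "labels must be 0 or 1; offending values: ",
          paste(utils::head(setdiff(unique(label), c(0, 1, "0", "1")), 5),
                collapse = ", "))
  label <- as.integer(label)
  key <- paste(drug_id, protein_id, sep = "\r")
  dup <- duplicated(key)
  stop_if(any(dup), "duplicate pair(s): ",
          paste(utils::head(sprintf("(%s,%s)", drug_id[dup], protein_id[dup]), 5),
                collapse = ", "))
  structure(data.frame(drug_id = drug_id, protein_id = protein_id,
                       label = label, stringsAsFactors = FALSE),
            provenance = provenance, class = c("dti_interactions", "data.frame"))
}

#' Read an interaction table
#'
#' Expects delimited text with header columns `drug_id`, `protein_id`,
#' `label` (labels strictly 0/1).
#'
#' @param path file path.
#' @param sep field separator.
#' @return A [dti_interactions] table.
#' @export
read_interactions <- function(path, sep = "\t") {
  stop_if(!file.exists(path), "file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("drug_id", "protein_id", "label")
  stop_if(!all(need %in% names(df)), "missing column(s): ",
          paste(setdiff(need, names(df)), collapse = ", "))
  dti_interactions(df$drug_id, df$protein_id, df$label, provenance = path)
}

#' Write an interaction table
#' @param tbl a [dti_interactions] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(tbl, path) {
  utils::write.table(tbl[, c("drug_id", "protein_id", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- sequence encoder adapters ----

encoder_registry <- new.env(parent = emptyenv())

#' Register a sequence encoder backend
#'
#' Backends turn raw sequences (amino-acid strings or SMILES) into embedding
#' matrices. External pretrained encoders can be plugged in here; the core
#' model never depends on any particular backend. A deterministic built-in
#' `"hash"` backend (seeded random projection of k-mer counts) always exists
#' so the full pipeline runs with no model download.
#'
#' @param name backend name.
#' @param fn function(sequences, modality, dim, seed) returning a numeric
#'   matrix with one row per sequence.
#' @return `name`, invisibly.
#' @export
register_encoder <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = encoder_registry)
  invisible(name)
}

#' List registered encoder backends
#' @return character vector of names.
#' @export
list_encoders <- function() sort(ls(encoder_registry))

# k-mer count hashing followed by a seeded Gaussian random projection;
# a pure function of (sequence, dim, seed).
hash_encoder <- function(sequences, modality, dim = 64, seed = 1, k = 3,
                         n_buckets = 512) {
  proj <- with_seed(derive_seed(seed, 17), {
    matrix(stats::rnorm(n_buckets * dim), n_buckets, dim) / sqrt(n_buckets)
  })
  emb <- matrix(0, length(sequences), dim)
  for (s in seq_along(sequences)) {
    x <- sequences[[s]]
    counts <- numeric(n_buckets)
    n <- nchar(x)
    kk <- min(k, n)
    for (i in seq_len(n - kk + 1L)) {
      kmer <- substr(x, i, i + kk - 1L)
      h <- sum(utf8ToInt(kmer) * 31^(seq_len(kk) - 1L)) %% n_buckets + 1L
      counts[h] <- counts[h] + 1
    }
    counts <- counts / max(1, sum(counts))
    emb[s, ] <- counts %*% proj
  }
  emb
}

#' Encode sequences with a registered backend
#'
#' @param sequences character vector (amino-acid sequences for proteins,
#'   SMILES strings for drugs); all non-empty.
#' @param modality `"protein"` or `"drug"`.
#' @param backend registered backend name (built-in: `"hash"`).
#' @param ids entity IDs (default `seq_along(sequences)` prefixed by modality).
#' @param dim embedding width.
#' @param seed seed passed to the backend.
#' @return A [dti_embeddings] object.
#' @export
encoder_adapter <- function(sequences, modality = c("protein", "drug"),
                            backend = "hash", ids = NULL, dim = 64, seed = 1) {
  modality <- match.arg(modality)
  stop_if(length(sequences) == 0, "no sequences given")
  stop_if(any(!nzchar(sequences)), "empty sequence at position ",
          which(!nzchar(sequences))[1L])
  if (!exists(backend, envir = encoder_registry)) {
    stop("unknown encoder backend '", backend, "'; registered: ",
         paste(list_encoders(), collapse = ", "), call. = FALSE)
  }
  fn <- get(backend, envir = encoder_registry)
  vals <- fn(sequences, modality, dim = dim, seed = seed)
  if (is.null(ids)) {
    ids <- paste0(substr(modality, 1, 1), seq_along(sequences))
  }
  dti_embeddings(ids, vals, modality)
}

#' Read protein sequences from a FASTA file
#'
#' Delegates to \pkg{Biostrings} when installed, otherwise falls back to a
#' minimal plain-text reader.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences (names = record IDs).
#' @export
read_fasta_sequences <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
    return(seqs)
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  stop_if(!any(hdr), "no FASTA records in ", path)
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  stats::setNames(seqs[as.character(seq_along(ids))], ids)
}

#' Read SMILES strings, one per line
#' @param path file path; optional second tab-separated field is the ID.
#' @return named character vector of SMILES.
#' @export
read_smiles_lines <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  smi <- vapply(parts, `[[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) > 1L) parts[[i]][[2L]] else paste0("d", i)
  }, character(1))
  stats::setNames(smi, ids)
}
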