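DNA_BASES <- c("A", "C", "G", "T")

#' DNA sequence object
#'
#' A length-validated DNA sequence over the alphabet `{A, C, G, T, N}`.
#' Input is case-insensitive and stored upper-case; `N` marks an unknown base
#' and one-hot encodes to an all-zero row.
#'
#' @param bases single character string of bases, length >= 1.
#' @param id sequence identifier.
#' @return an object of class `dna_sequence` with fields `id` and `bases`.
#' @export
#' @examples
#' dna_sequence("acgtn", id = "chr1_window_1")
dna_sequence <- function(bases, id = "seq") {
  if (!is.character(bases) || length(bases) != 1L || is.na(bases)) {
    stopf("bases must be a single character string")
  }
  b <- toupper(bases)
  if (nchar(b) < 1L) stopf("sequence '%s' is empty", id)
  chars <- strsplit(b, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c(DNA_BASES, "N"))
  if (length(bad)) {
    stopf(
      "invalid symbol '%s' at position %d in sequence '%s' (allowed: A,C,G,T,N)",
      chars[bad[1L]], bad[1L], id
    )
  }
  structure(list(id = as.character(id), bases = b), class = "dna_sequence")
}

#' @export
print.dna_sequence <- function(x, ...) {
  cat(sprintf("<dna_sequence %s: %d nt>\n", x$id, nchar(x$bases)))
  invisible(x)
}

#' One-hot encode a DNA sequence
#'
#' Encodes a sequence as an L x 4 binary matrix in the fixed channel order
#' (A, C, G, T); row t is the unit vector for base t, `N` rows are all zero.
#' The length-major L x 4 layout is the internal convention throughout the
#' package (the channel-major 4 x L layout used by some pipelines is its
#' transpose; see [as_one_hot()]).
#'
#' @param seq a [dna_sequence()] or a plain character string.
#' @return an L x 4 0/1 matrix with colnames `A,C,G,T`.
#' @export
#' @examples
#' one_hot_encode("ACGT")  # 4 x 4 identity
one_hot_encode <- function(seq) {
  if (is.character(seq)) seq <- dna_sequence(seq)
  if (!inherits(seq, "dna_sequence")) stopf("seq must be a dna_sequence or string")
  chars <- strsplit(seq$bases, "", fixed = TRUE)[[1L]]
  idx <- match(chars, DNA_BASES)   # NA for N (validated at construction)
  m <- matrix(0, length(chars), 4L, dimnames = list(NULL, DNA_BASES))
  hit <- which(!is.na(idx))
  m[cbind(hit, idx[hit])] <- 1
  m
}

#' Decode a one-hot matrix back to a DNA sequence
#'
#' Inverse of [one_hot_encode()]: unit rows map to their base, all-zero rows
#' map to `N`.
#'
#' @param m L x 4 matrix with 0/1 entries and row sums in `{0, 1}`.
#' @param id identifier for the decoded sequence.
#' @return a [dna_sequence()].
#' @export
decode_one_hot <- function(m, id = "seq") {
  m <- as_one_hot(m, orientation = "length_major")
  rs <- rowSums(m)
  bad <- which(rs > 1)
  if (length(bad)) {
    stopf("malformed one-hot matrix: row %d sums to %g (> 1)", bad[1L], rs[bad[1L]])
  }
  j <- as.integer(m %*% seq_len(4L))      # 0 for all-zero rows
  chars <- ifelse(rs == 0, "N", DNA_BASES[pmax(j, 1L)])
  dna_sequence(paste(chars, collapse = ""), id = id)
}

#' Coerce a matrix to the internal length-major one-hot layout
#'
#' Accepts either an L x 4 (length-major) or 4 x L (channel-major) 0/1 matrix
#' and returns the length-major form. A 4 x 4 input is ambiguous and requires
#' an explicit `orientation`.
#'
#' @param m numeric matrix of 0/1 entries.
#' @param orientation `"auto"` (detect by which axis has size 4),
#'   `"length_major"` (rows are positions) or `"channel_major"` (rows are the
#'   A,C,G,T channels).
#' @return an L x 4 matrix.
#' @export
as_one_hot <- function(m, orientation = c("auto", "length_major", "channel_major")) {
  orientation <- match.arg(orientation)
  if (!is.matrix(m) || !is.numeric(m)) stopf("m must be a numeric matrix")
  if (!all(m %in% c(0, 1))) stopf("one-hot matrix entries must be 0 or 1")
  if (orientation == "auto") {
    if (ncol(m) == 4L && nrow(m) == 4L) {
      stopf("4 x 4 one-hot matrix is ambiguous; pass orientation explicitly")
    }
    if (ncol(m) == 4L) orientation <- "length_major"
    else if (nrow(m) == 4L) orientation <- "channel_major"
    else stopf("matrix %d x %d has no axis of size 4", nrow(m), ncol(m))
  }
  out <- if (orientation == "channel_major") t(m) else m
  if (ncol(out) != 4L) stopf("one-hot matrix must have 4 channels, got %d", ncol(out))
  colnames(out) <- DNA_BASES
  out
}

#' Random train/validation split
#'
#' Shuffles `0..n-1`-style indices (1-based here) under `seed` and splits them
#' into a training and a validation partition; the training size is
#' `round(frac * n)` with round-half-up, clamped so both partitions are
#' non-empty. 92/8 is the conventional split for this task.
#'
#' @param n number of samples, >= 2.
#' @param frac training fraction in (0, 1); default 0.92.
#' @param seed integer seed; the split is deterministic given (n, frac, seed).
#' @return a `dataset_split`: list with sorted `train_idx`, `val_idx`, `frac`,
#'   `seed`.
#' @export
#' @examples
#' split_train_val(100, seed = 1)  # 92 train / 8 validation
split_train_val <- function(n, frac = 0.92, seed = 1L) {
  if (!is_count(n, min = 2L)) stopf("n must be an integer >= 2 (cannot form both partitions)")
  if (!is.numeric(frac) || length(frac) != 1L || frac <= 0 || frac >= 1) {
    stopf("frac must lie strictly in (0, 1)")
  }
  n <- as.integer(n)
  n_train <- as.integer(floor(frac * n + 0.5))   # round half up
  n_train <- max(1L, min(n - 1L, n_train))
  perm <- with_seed(seed, sample.int(n))
  structure(
    list(
      train_idx = sort(perm[seq_len(n_train)]),
      val_idx   = sort(perm[(n_train + 1L):n]),
      frac = frac,
      seed = as.integer(seed)
    ),
    class = "dataset_split"
  )
}

#' Read DNA sequences from a FASTA file
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return list of [dna_sequence()] objects in file order; ids are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: '%s'", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stopf("failed to parse FASTA '%s': %s", path, conditionMessage(e))
  )
  ids <- sub("\\s.*$", "", names(set) %||% as.character(seq_along(set)))
  lapply(seq_along(set), function(i) {
    tryCatch(
      dna_sequence(as.character(set[[i]]), id = ids[[i]]),
      error = function(e) stopf("record %d of '%s': %s", i, path, conditionMessage(e))
    )
  })
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs list of [dna_sequence()] objects or a named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    v <- seqs
    if (is.null(names(v))) names(v) <- paste0("seq", seq_along(v))
  } else {
    v <- vapply(seqs, function(s) s$bases, character(1L))
    names(v) <- vapply(seqs, function(s) s$id, character(1L))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(v), path)
  invisible(path)
}

#' Multi-label class membership matrix
#'
#' @param values n x C matrix with 0/1 entries; rows are sequences, columns
#'   classes (e.g. transcription factors).
#' @param class_names character vector of C class names.
#' @param ids optional sequence identifiers (length n).
#' @return a `label_matrix` object.
#' @export
label_matrix <- function(values, class_names = colnames(values), ids = rownames(values)) {
  values <- as.matrix(values)
  if (!all(values %in% c(0, 1))) stopf("label entries must be 0 or 1")
  if (ncol(values) < 1L) stopf("need at least one class")
  if (is.null(class_names)) class_names <- paste0("class", seq_len(ncol(values)))
  if (length(class_names) != ncol(values)) {
    stopf("class_names length %d != %d classes", length(class_names), ncol(values))
  }
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  structure(
    list(values = values, class_names = as.character(class_names),
         ids = if (is.null(ids)) NULL else as.character(ids)),
    class = "label_matrix"
  )
}

label_values <- function(y) {
  if (inherits(y, "label_matrix")) y$values else as.matrix(y)
}

#' Read a tab-separated label file
#'
#' Expected layout: header row with `id` plus one column per class; body rows
#' hold the sequence id and C binary labels.
#'
#' @param path path to the TSV file.
#' @return a [label_matrix()].
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stopf("label file not found: '%s'", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("label file '%s' needs an id column plus >= 1 class column", path)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  label_matrix(vals, class_names = colnames(df)[-1L], ids = as.character(df[[1L]]))
}

#' Write a label matrix as TSV
#' @param labels a [label_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_matrix"))
  ids <- labels$ids %||% paste0("seq", seq_len(nrow(labels$values)))
  df <- data.frame(id = ids, labels$values, check.names = FALSE)
  colnames(df) <- c("id", labels$class_names)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Encode equal-length sequences into a one-hot tensor
#'
#' @param seqs list of [dna_sequence()] objects or character vector, all the
#'   same length L.
#' @return numeric array of dim `(L, 4, n)`.
#' @export
encode_sequences <- function(seqs) {
  if (is.character(seqs)) seqs <- lapply(seqs, dna_sequence)
  n <- length(seqs)
  if (n == 0L) stopf("no sequences to encode")
  lens <- vapply(seqs, function(s) nchar(s$bases), integer(1L))
  if (length(unique(lens)) != 1L) {
    stopf("sequences must share one length; saw lengths %s", paste(unique(lens), collapse = ", "))
  }
  L <- lens[1L]
  x <- array(0, c(L, 4L, n))
  for (i in seq_len(n)) x[, , i] <- one_hot_encode(seqs[[i]])
  x
}

#' Assemble an encoded dataset container
#'
#' Bundles the one-hot tensor, label matrix, class names, sequence ids and an
#' optional train/validation split into the container consumed by
#' [train_network()] and the CLI.
#'
#' @param x one-hot array of dim `(L, 4, n)`.
#' @param labels a [label_matrix()] with n rows.
#' @param split optional [split_train_val()] result over n samples.
#' @return a `cac_dataset` object.
#' @export
cac_dataset <- function(x, labels, split = NULL) {
  stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[2L] == 4L)
  stopifnot(inherits(labels, "label_matrix"))
  if (dim(x)[3L] != nrow(labels$values)) {
    stopf("tensor holds %d sequences but labels have %d rows", dim(x)[3L], nrow(labels$values))
  }
  if (!is.null(split)) {
    stopifnot(inherits(split, "dataset_split"))
    if (length(split$train_idx) + length(split$val_idx) != dim(x)[3L]) {
      stopf("split covers %d samples, dataset has %d",
            length(split$train_idx) + length(split$val_idx), dim(x)[3L])
    }
  }
  structure(list(x = x, labels = labels, split = split), class = "cac_dataset")
}

#' @export
print.cac_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<cac_dataset: %d sequences x %d nt, %d classes%s>\n",
              d[3L], d[1L], ncol(x$labels$values),
              if (is.null(x$split)) "" else sprintf(", split %d/%d",
                length(x$split$train_idx), length(x$split$val_idx))))
  invisible(x)
}

#' Persist / restore a dataset container
#'
#' Round trip is bitwise exact for the tensor and label matrix.
#'
#' @param dataset a [cac_dataset()].
#' @param path file path (RDS).
#' @return `save_dataset` returns `path` invisibly; `load_dataset` the dataset.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "cac_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stopf("dataset file not found: '%s'", path)
  x <- readRDS(path)
  if (!inherits(x, "cac_dataset")) stopf("'%s' does not contain a cac_dataset", path)
  x
}

#' Extract (x, y) tensors for a subset of samples
#'
#' @param dataset a [cac_dataset()].
#' @param idx sample indices (default: all).
#' @return list with `x` (one-hot array) and `y` (label matrix), the shape
#'   consumed by [train_network()].
#' @export
dataset_tensors <- function(dataset, idx = NULL) {
  stopifnot(inherits(dataset, "cac_dataset"))
  if (is.null(idx)) idx <- seq_len(dim(dataset$x)[3L])
  list(
    x = dataset$x[, , idx, drop = FALSE],
    y = dataset$labels$values[idx, , drop = FALSE]
  )
}
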