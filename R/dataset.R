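# Training-pool construction: class balancing by undersampling, the two
# split designs (segment-wise random, patient-wise record-disjoint) and
# stratified k-fold plans. All sampling is seeded and ties are broken by
# (record_id, segment_index) so identical inputs give byte-identical
# manifests.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# canonical ordering used before every seeded draw
canonical_order <- function(ds) {
  order(ds$record_id, ds$segment_index)
}

#' Balance a dataset by undersampling each class
#'
#' Draws exactly `n_per_class` members of each class uniformly without
#' replacement (seeded); everything not drawn forms the leftover pool, which
#' the evaluation protocol sends to the test side.
#'
#' @param ds a [segment_dataset()].
#' @param n_per_class segments to keep per class.
#' @param seed integer seed.
#' @return A list with elements `pool` (balanced `segment_dataset`) and
#'   `leftover` (the complement).
#' @export
undersample_balance <- function(ds, n_per_class, seed = 1L) {
  stopifnot(inherits(ds, "segment_dataset"))
  ord <- canonical_order(ds)
  idx_by_class <- split(ord, ds$label[ord])
  for (cls in names(idx_by_class)) {
    if (length(idx_by_class[[cls]]) < n_per_class) {
      stop(sprintf(
        "class '%s' has only %d segments; cannot undersample to %d",
        cls, length(idx_by_class[[cls]]), n_per_class), call. = FALSE)
    }
  }
  keep <- with_seed(seed, {
    unlist(lapply(idx_by_class, function(ix) sort(sample(ix, n_per_class))))
  })
  keep <- sort(keep)
  list(pool = subset_segments(ds, keep),
       leftover = subset_segments(ds, setdiff(seq_len(n_segments(ds)), keep)))
}

split_ids <- function(ds, i) {
  data.frame(record_id = ds$record_id[i], segment_index = ds$segment_index[i],
             label = as.character(ds$label[i]), stringsAsFactors = FALSE)
}

new_split <- function(train, validation, test, mode, seed) {
  structure(list(train = train, validation = validation, test = test,
                 mode = mode, seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split mode='%s'> train %d / validation %d / test %d\n",
              x$mode, nrow(x$train), nrow(x$validation), nrow(x$test)))
  invisible(x)
}

#' Random segment-wise split, stratified by class
#'
#' Assigns segments at random to train / validation / test, independently
#' within each class so every part keeps the pool's class proportions (to
#' within one member per class). Segments from one recording may land on
#' different sides: this is the conventional hold-out design and is exactly
#' the identity-leakage scenario the patient-wise design removes.
#'
#' @param ds a [segment_dataset()].
#' @param train_fraction,val_fraction fractions in (0,1), summing to at most
#'   1; the remainder is the test part.
#' @param seed integer seed.
#' @return A `dataset_split` with data-frame parts of
#'   (record_id, segment_index, label).
#' @export
split_segmentwise <- function(ds, train_fraction = 0.7, val_fraction = 0.3,
                              seed = 1L) {
  stopifnot(inherits(ds, "segment_dataset"))
  if (train_fraction <= 0 || train_fraction > 1 || val_fraction < 0 ||
      train_fraction + val_fraction > 1 + 1e-12) {
    stop("fractions must lie in (0,1] and sum to at most 1", call. = FALSE)
  }
  if (any(table(ds$label) == 0L)) {
    stop("both classes must be present to stratify", call. = FALSE)
  }
  ord <- canonical_order(ds)
  idx_by_class <- split(ord, ds$label[ord])
  parts <- with_seed(seed, {
    lapply(idx_by_class, function(ix) {
      ix <- sample(ix)
      n <- length(ix)
      n_tr <- round(train_fraction * n)
      n_va <- min(round(val_fraction * n), n - n_tr)
      list(train = ix[seq_len(n_tr)],
           validation = if (n_va > 0L) ix[n_tr + seq_len(n_va)] else integer(),
           test = if (n_tr + n_va < n) ix[(n_tr + n_va + 1L):n] else integer())
    })
  })
  take <- function(part) {
    i <- sort(unlist(lapply(parts, `[[`, part), use.names = FALSE))
    split_ids(ds, i)
  }
  new_split(take("train"), take("validation"), take("test"),
            mode = "segmentwise", seed = seed)
}

#' Patient-wise (record-disjoint) split
#'
#' Every segment of a recording lands on the same side: recordings named in
#' `train_record_ids` contribute all their segments to the train side, all
#' other recordings to the test side. Because each recording belongs to one
#' patient, no patient's signal is seen both in training and in evaluation.
#'
#' @param ds a [segment_dataset()].
#' @param train_record_ids character vector, a non-empty proper subset of the
#'   dataset's record ids.
#' @param seed integer seed recorded in the split (no randomness is used).
#' @return A `dataset_split` in `"patientwise"` mode (validation empty; carve
#'   a validation share from the train side per class with
#'   [split_segmentwise()] on the train subset if needed).
#' @export
split_patientwise <- function(ds, train_record_ids, seed = 1L) {
  stopifnot(inherits(ds, "segment_dataset"))
  all_ids <- unique(ds$record_id)
  unknown <- setdiff(train_record_ids, all_ids)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown record id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (length(train_record_ids) == 0L ||
      length(setdiff(all_ids, train_record_ids)) == 0L) {
    stop("`train_record_ids` must be a non-empty proper subset of records",
         call. = FALSE)
  }
  in_train <- ds$record_id %in% train_record_ids
  ord <- canonical_order(ds)
  new_split(split_ids(ds, ord[in_train[ord]]),
            split_ids(ds, integer()),
            split_ids(ds, ord[!in_train[ord]]),
            mode = "patientwise", seed = seed)
}

#' Audit a split for patient-identity leakage
#'
#' @param split a `dataset_split`.
#' @return character vector of record ids present on both the train (or
#'   validation) side and the test side — empty iff the split is leak-free.
#' @export
audit_split_leakage <- function(split) {
  stopifnot(inherits(split, "dataset_split"))
  intersect(unique(c(split$train$record_id, split$validation$record_id)),
            unique(split$test$record_id))
}

#' Stratified k-fold partition plan
#'
#' Partitions ids into `k` folds of sizes differing by at most one,
#' stratified by label, for cross-validation in which each fold serves once
#' as the validation set; no id appears in both the training and validation
#' side of any round.
#'
#' @param ids data frame with columns `record_id`, `segment_index`, `label`
#'   (as produced in split parts), or a [segment_dataset()].
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @param stratify stratify fold assignment by label (default TRUE).
#' @return A `fold_plan`: `ids` plus a `fold` column in `1..k`.
#' @export
make_folds <- function(ids, k = 10L, seed = 1L, stratify = TRUE) {
  if (inherits(ids, "segment_dataset")) {
    ids <- split_ids(ids, canonical_order(ids))
  }
  n <- nrow(ids)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop(sprintf("k = %d exceeds the %d available ids", k, n),
                  call. = FALSE)
  ids <- ids[order(ids$record_id, ids$segment_index), , drop = FALSE]
  fold <- integer(n)
  groups <- if (stratify) split(seq_len(n), ids$label) else list(seq_len(n))
  with_seed(seed, {
    offset <- 0L
    for (g in groups) {
      # continue the fold cycle across strata so total sizes stay within 1
      f <- ((offset + seq_along(g) - 1L) %% k) + 1L
      fold[sample(g)] <- f
      offset <- (offset + length(g)) %% k
    }
  })
  ids$fold <- fold
  rownames(ids) <- NULL
  structure(list(ids = ids, k = as.integer(k), seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d ids in %d folds (sizes %s)\n", nrow(x$ids),
              x$k, paste(tabulate(x$ids$fold, x$k), collapse = "/")))
  invisible(x)
}

#' Thin a test pool to a target class composition
#'
#' Keeps every member of the smaller-represented target class and draws the
#' complement so the result has the requested normal share, e.g. the 60/40
#' normal/anomalous composition of the conventional hold-out evaluation.
#'
#' @param ds a [segment_dataset()] (the candidate test pool).
#' @param normal_fraction target share of normal segments (default 0.6).
#' @param n_normal optional exact number of normal segments to keep; the
#'   anomalous count is then derived from `normal_fraction`.
#' @param seed integer seed.
#' @return A `segment_dataset` with the requested composition.
#' @export
subsample_test <- function(ds, normal_fraction = 0.6, n_normal = NULL,
                           seed = 1L) {
  stopifnot(inherits(ds, "segment_dataset"),
            normal_fraction > 0, normal_fraction < 1)
  ord <- canonical_order(ds)
  norm_ix <- ord[ds$label[ord] == "normal"]
  anom_ix <- ord[ds$label[ord] == "anomalous"]
  if (is.null(n_normal)) n_normal <- length(norm_ix)
  n_anom <- round(n_normal * (1 - normal_fraction) / normal_fraction)
  if (n_normal > length(norm_ix) || n_anom > length(anom_ix)) {
    stop(sprintf(
      "requested %d normal + %d anomalous but only %d + %d available",
      n_normal, n_anom, length(norm_ix), length(anom_ix)), call. = FALSE)
  }
  keep <- with_seed(seed, {
    c(sample(norm_ix, n_normal), sample(anom_ix, n_anom))
  })
  subset_segments(ds, sort(keep))
}

#' Write a split (or fold plan) manifest
#'
#' One row per segment: `record_id, segment_index, label, partition, fold`.
#' Rows are ordered by partition then (record_id, segment_index), so the
#' same split always produces a byte-identical file.
#'
#' @param split a `dataset_split` or `fold_plan`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  if (inherits(split, "fold_plan")) {
    df <- split$ids
    df$partition <- "pool"
    df <- df[, c("record_id", "segment_index", "label", "partition", "fold")]
  } else {
    stopifnot(inherits(split, "dataset_split"))
    part <- function(p, nm) {
      if (nrow(p) == 0L) return(NULL)
      cbind(p, partition = nm, fold = NA_integer_)
    }
    df <- rbind(part(split$train, "train"),
                part(split$validation, "validation"),
                part(split$test, "test"))
  }
  df <- df[order(df$partition, df$record_id, df$segment_index), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a split manifest written by [write_split_manifest()]
#'
#' @param path manifest CSV path.
#' @return A data frame (record_id, segment_index, label, partition, fold).
#' @export
read_split_manifest <- function(path) {
  df <- read_table_sniffed(path)
  df$record_id <- as.character(df$record_id)
  df
}

#' Row indices of a dataset matching one manifest partition
#'
#' @param ds a [segment_dataset()].
#' @param manifest data frame from [read_split_manifest()] or a split part.
#' @param partition partition name to select, or NULL for all rows.
#' @return integer row indices into `ds`.
#' @export
match_manifest <- function(ds, manifest, partition = NULL) {
  stopifnot(inherits(ds, "segment_dataset"))
  if (!is.null(partition)) {
    manifest <- manifest[manifest$partition == partition, , drop = FALSE]
  }
  key_ds <- paste(ds$record_id, ds$segment_index, sep = "#")
  key_mf <- paste(manifest$record_id, manifest$segment_index, sep = "#")
  i <- match(key_mf, key_ds)
  if (anyNA(i)) {
    stop(sprintf("%d manifest row(s) not present in the dataset", sum(is.na(i))),
         call. = FALSE)
  }
  i
}
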