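SPOT_TYPES <- c("peptide", "positive_control", "negative_control", "blank")

#' Build the default subarray layout
#'
#' One 9 x 9 subarray (block) per membrane carrying one spot per panel
#' peptide, four positive-control spots (printed human IgG), one
#' negative-control spot (printing buffer) and eight blank positions used
#' for background estimation. Spots fill the grid row-major; the grid need
#' not be full. Within-block peptide replication is configurable.
#'
#' @param peptides character vector of peptide probe names.
#' @param n_row,n_col block grid dimensions (default 9 x 9).
#' @param n_pos number of positive-control spots (default 4).
#' @param n_neg number of negative-control spots (default 1).
#' @param n_blank number of blank spots (default 8).
#' @param peptide_replicates spots per peptide within the block (default 1).
#' @param n_block number of blocks per array (default 1).
#' @return layout `data.frame` with columns `block`, `row`, `column`,
#'   `probe_id`, `spot_type`.
#' @export
default_layout <- function(peptides, n_row = 9L, n_col = 9L, n_pos = 4L,
                           n_neg = 1L, n_blank = 8L, peptide_replicates = 1L,
                           n_block = 1L) {
  probes <- c(
    rep(peptides, each = peptide_replicates),
    rep("POS", n_pos), rep("NEG", n_neg), rep("BLANK", n_blank)
  )
  types <- c(
    rep("peptide", length(peptides) * peptide_replicates),
    rep("positive_control", n_pos),
    rep("negative_control", n_neg),
    rep("blank", n_blank)
  )
  n_spot <- length(probes)
  if (n_spot > n_row * n_col) {
    stop_ps("layout needs %d spots but the block only has %d positions",
            n_spot, n_row * n_col)
  }
  idx <- seq_len(n_spot) - 1L
  one <- data.frame(
    row = idx %/% n_col + 1L,
    column = idx %% n_col + 1L,
    probe_id = probes,
    spot_type = types,
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(seq_len(n_block), function(b) {
    cbind(block = b, one)
  }))
  rownames(out) <- NULL
  out[, c("block", "row", "column", "probe_id", "spot_type")]
}

#' Parse and validate an array layout table
#'
#' GAL-like TSV with columns `block`, `row`, `column`, `probe_id`,
#' `spot_type` (spot types: peptide, positive_control, negative_control,
#' blank). Rejects duplicate grid coordinates, unknown spot types and —
#' when a panel is supplied — peptide probes absent from the panel.
#'
#' @param layout path to a layout TSV, or an equivalent `data.frame`.
#' @param panel optional character vector of valid peptide probe names.
#' @return validated layout `data.frame`; per-block spot-type counts are
#'   attached as attribute `"block_counts"`.
#' @export
parse_layout <- function(layout, panel = NULL) {
  if (is.character(layout)) {
    if (file.info(layout)$size == 0) stop_ps("layout file '%s' is empty", layout)
    layout <- utils::read.delim(layout, stringsAsFactors = FALSE)
  }
  if (nrow(layout) == 0L) stop_ps("layout has no spots")
  check_columns(layout, c("block", "row", "column", "probe_id", "spot_type"),
                "layout")
  bad_type <- !(layout$spot_type %in% SPOT_TYPES)
  if (any(bad_type)) {
    stop_ps("unknown spot_type '%s' at layout row %d",
            layout$spot_type[which(bad_type)[1]], which(bad_type)[1])
  }
  key <- paste(layout$block, layout$row, layout$column)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop_ps("duplicate layout coordinate (block,row,column) = (%s)",
            gsub(" ", ",", d))
  }
  if (!is.null(panel)) {
    pep <- layout$spot_type == "peptide"
    unknown <- !(layout$probe_id[pep] %in% panel)
    if (any(unknown)) {
      row_no <- which(pep)[which(unknown)[1]]
      stop_ps("peptide probe '%s' (layout row %d) is not in the panel",
              layout$probe_id[row_no], row_no)
    }
  }
  counts <- as.data.frame(table(block = layout$block, spot_type = layout$spot_type))
  attr(layout, "block_counts") <- counts
  layout
}

#' Write a layout table as TSV
#' @param layout layout `data.frame`.
#' @param path output file.
#' @export
write_layout <- function(layout, path) {
  utils::write.table(layout[, c("block", "row", "column", "probe_id", "spot_type")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-array spot intensity table
#'
#' GPR-like TSV with columns `block`, `row`, `column`, `probe_id`,
#' `intensity` (median chemiluminescence per spot, arbitrary units).
#'
#' @param path intensity TSV.
#' @return spot `data.frame`.
#' @export
read_spots <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("block", "row", "column", "probe_id", "intensity"), path)
  if (any(!is.finite(df$intensity)) || any(df$intensity < 0)) {
    stop_ps("'%s' contains negative or non-finite intensities", path)
  }
  df
}

#' Mean blank-spot background
#'
#' Background is the arithmetic mean of the blank-spot intensities of a
#' subarray (the design prints eight blanks per block; a deviating count is
#' reported as a warning, not an error).
#'
#' @param blank_intensities numeric vector of blank-spot intensities.
#' @param expected_blanks blank count the design expects (default 8).
#' @return background intensity (scalar, > 0).
#' @export
compute_background <- function(blank_intensities, expected_blanks = 8L) {
  blank_intensities <- blank_intensities[is.finite(blank_intensities)]
  if (length(blank_intensities) == 0L) stop_ps("no blank spots: background undefined")
  if (length(blank_intensities) != expected_blanks) {
    warn_ps("expected %d blank spots, found %d", expected_blanks,
            length(blank_intensities))
  }
  bg <- mean(blank_intensities)
  if (bg <= 0) stop_ps("blank background is %g; SNR would be undefined", bg)
  bg
}

#' Signal-to-noise ratio of a spot
#'
#' SNR = (signal - background) / background. Dimensionless; negative when
#' the spot is dimmer than the blanks (values are deliberately not floored
#' at zero so the cut-off search sees the full distribution).
#'
#' @param signal spot intensity (>= 0), vectorized.
#' @param background blank-spot background (> 0), scalar or vector.
#' @return SNR value(s).
#' @export
compute_snr <- function(signal, background) {
  if (any(!is.finite(background)) || any(background <= 0)) {
    stop_ps("background must be positive and finite")
  }
  if (any(!is.finite(signal)) || any(signal < 0)) {
    stop_ps("signal intensity must be non-negative and finite")
  }
  (signal - background) / background
}

# join spots to layout, compute per-block background and per-spot SNR
quantify_array <- function(layout, spots) {
  key_l <- paste(layout$block, layout$row, layout$column)
  key_s <- paste(spots$block, spots$row, spots$column)
  m <- match(key_s, key_l)
  if (anyNA(m)) {
    stop_ps("spot at (block,row,column) = (%s) is absent from the layout",
            gsub(" ", ",", key_s[which(is.na(m))[1]]))
  }
  spots$spot_type <- layout$spot_type[m]
  bg <- vapply(split(spots, spots$block), function(b) {
    compute_background(b$intensity[b$spot_type == "blank"])
  }, numeric(1))
  spots$background <- bg[as.character(spots$block)]
  spots$snr <- compute_snr(spots$intensity, spots$background)
  spots
}

#' Control-based array quality control
#'
#' Computes per-block blank background and control SNRs, and passes the
#' array iff every positive-control SNR reaches `min_pos_snr` and every
#' negative-control SNR stays at or below `max_neg_snr`. Missing control
#' spots fail QC with a reason rather than raising an error, so a damaged
#' array is excluded from aggregation but does not abort a run.
#'
#' @param layout validated layout (see [parse_layout()]).
#' @param spots spot table for one array (see [read_spots()]).
#' @param min_pos_snr minimum acceptable positive-control SNR (default 2).
#' @param max_neg_snr maximum acceptable negative-control SNR (default 1).
#' @return list with `background` (per block), `positive_control_snr`,
#'   `negative_control_snr`, `pass` flag, `reasons` (character), and the
#'   per-spot quantification in `spots` (NULL when background fails).
#' @export
qc_array <- function(layout, spots, min_pos_snr = 2, max_neg_snr = 1) {
  reasons <- character(0)
  q <- tryCatch(quantify_array(layout, spots), error = function(e) {
    reasons <<- c(reasons, conditionMessage(e))
    NULL
  })
  if (is.null(q)) {
    return(list(background = NA_real_, positive_control_snr = numeric(0),
                negative_control_snr = numeric(0), pass = FALSE,
                reasons = reasons, spots = NULL))
  }
  pos <- q$snr[q$spot_type == "positive_control"]
  neg <- q$snr[q$spot_type == "negative_control"]
  if (length(pos) == 0L) reasons <- c(reasons, "missing control: no positive-control spots")
  if (length(neg) == 0L) reasons <- c(reasons, "missing control: no negative-control spots")
  low <- which(pos < min_pos_snr)
  if (length(low) > 0L) {
    reasons <- c(reasons, sprintf(
      "positive control %d SNR %.3g below threshold %.3g", low, pos[low], min_pos_snr))
  }
  high <- which(neg > max_neg_snr)
  if (length(high) > 0L) {
    reasons <- c(reasons, sprintf(
      "negative control %d SNR %.3g above threshold %.3g", high, neg[high], max_neg_snr))
  }
  bg <- c(tapply(q$background, q$block, function(x) x[1]))
  list(background = bg, positive_control_snr = pos, negative_control_snr = neg,
       pass = length(reasons) == 0L, reasons = reasons, spots = q)
}

#' Aggregate replicate arrays into a per-serum reactivity profile
#'
#' Each serum is assayed on replicate arrays (two in the emulated design);
#' the per-peptide SNR of the serum is the arithmetic mean over QC-passing
#' replicates. A peptide measured on only one passing replicate keeps that
#' single value; a serum with no passing replicate is returned with
#' `n_replicates = 0` and all-NA SNR so downstream stages can skip it
#' explicitly.
#'
#' @param replicate_snr list of per-replicate named numeric vectors
#'   (peptide name -> SNR), QC-passing replicates only.
#' @param panel character vector of panel peptide names (defines profile
#'   rows and their order).
#' @return `data.frame` with columns `peptide`, `snr`, `n_replicates`.
#' @export
aggregate_replicates <- function(replicate_snr, panel) {
  if (length(replicate_snr) == 0L) {
    return(data.frame(peptide = panel, snr = NA_real_, n_replicates = 0L,
                      stringsAsFactors = FALSE))
  }
  vals <- vapply(panel, function(p) {
    x <- unlist(lapply(replicate_snr, function(r) r[[p]]))
    x <- x[!is.na(x)]
    if (length(x) == 0L) c(NA_real_, 0) else c(mean(x), length(x))
  }, numeric(2))
  data.frame(peptide = panel, snr = vals[1, ], n_replicates = as.integer(vals[2, ]),
             stringsAsFactors = FALSE)
}

#' Read an array manifest
#'
#' CSV mapping intensity files to sera: columns `file`, `serum_id`,
#' `replicate`, `group`, `timepoint`.
#'
#' @param path manifest CSV.
#' @return manifest `data.frame`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("file", "serum_id", "replicate", "group", "timepoint"), path)
  df
}

#' Quantify a whole cohort of arrays into reactivity profiles
#'
#' Runs per-array quantification + QC and replicate aggregation for every
#' serum/timepoint in a manifest. Arrays may be given as files on disk
#' (manifest `file` column relative to `dir`) or as an in-memory named list
#' of spot tables.
#'
#' @param manifest manifest `data.frame` (see [read_manifest()]).
#' @param layout validated layout.
#' @param panel peptide probe names.
#' @param dir directory containing the per-array intensity TSVs (ignored
#'   when `arrays` is given).
#' @param arrays optional named list of spot `data.frame`s keyed by
#'   manifest `file`.
#' @param min_pos_snr,max_neg_snr QC thresholds (see [qc_array()]).
#' @return list with `profiles` (long `data.frame`: `serum_id`, `group`,
#'   `timepoint`, `peptide`, `snr`, `n_replicates`) and `qc` (one row per
#'   array: pass flag and reasons).
#' @export
build_profiles <- function(manifest, layout, panel, dir = NULL, arrays = NULL,
                           min_pos_snr = 2, max_neg_snr = 1) {
  get_spots <- function(f) {
    if (!is.null(arrays)) {
      if (is.null(arrays[[f]])) stop_ps("array '%s' missing from supplied list", f)
      arrays[[f]]
    } else {
      path <- file.path(dir, f)
      if (!file.exists(path)) stop_ps("intensity file '%s' not found", path)
      read_spots(path)
    }
  }
  qc_rows <- vector("list", nrow(manifest))
  snr_by_array <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    # read eagerly: a missing/unreadable file is a hard input error, not a
    # QC failure (qc_array only absorbs within-array quantification faults)
    spots_i <- get_spots(manifest$file[i])
    qc <- qc_array(layout, spots_i, min_pos_snr, max_neg_snr)
    qc_rows[[i]] <- data.frame(
      file = manifest$file[i], serum_id = manifest$serum_id[i],
      replicate = manifest$replicate[i], timepoint = manifest$timepoint[i],
      pass = qc$pass, reasons = paste(qc$reasons, collapse = "; "),
      stringsAsFactors = FALSE
    )
    if (qc$pass) {
      pep <- qc$spots[qc$spots$spot_type == "peptide", ]
      snr_by_array[[i]] <- tapply(pep$snr, pep$probe_id, mean)
    }
  }
  qc_log <- do.call(rbind, qc_rows)
  sample_key <- paste(manifest$serum_id, manifest$timepoint, sep = "\r")
  profiles <- lapply(unique(sample_key), function(k) {
    idx <- which(sample_key == k)
    passing <- Filter(Negate(is.null), snr_by_array[idx])
    prof <- aggregate_replicates(passing, panel)
    cbind(serum_id = manifest$serum_id[idx[1]], group = manifest$group[idx[1]],
          timepoint = manifest$timepoint[idx[1]], prof,
          stringsAsFactors = FALSE)
  })
  profiles <- do.call(rbind, profiles)
  rownames(profiles) <- NULL
  list(profiles = profiles, qc = qc_log)
}

#' Write / read long-format reactivity profiles (TSV)
#' @param profiles profile `data.frame` from [build_profiles()].
#' @param path TSV path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("serum_id", "group", "timepoint", "peptide", "snr"), path)
  df
}
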