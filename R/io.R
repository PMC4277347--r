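#' Read a bird table
#'
#' Reads the per-specimen table of a cohort: one row per bird with its
#' identifier, provenance (`bycatch`, `reference_ys`, `reference_bs`), sex,
#' collection date, plumage call, the six biometric measurements (mm) and the
#' four feather stable-isotope values (permil). The delimiter is auto-detected
#' among comma and tab unless given.
#'
#' Missing cells become `NA`, never zeros. Column names must match the
#' canonical bird-table header (see [write_bird_table()]); extra columns are
#' preserved.
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field delimiter; `NULL` (default) auto-detects comma vs tab.
#' @return A `data.frame` of class `bird_table`, one row per specimen.
#' @seealso [write_bird_table()], [simulate_cohort()]
#' @export
read_bird_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_ctx("bird table not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          check.names = FALSE)
  validate_bird_table(df)
}

#' Write a bird table
#'
#' @param birds A bird table (`data.frame`).
#' @param path Output path.
#' @param sep Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_bird_table <- function(birds, path, sep = ",") {
  utils::write.table(birds, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

# Check field types, enum tokens, id uniqueness and value ranges.
validate_bird_table <- function(df) {
  if (!"id" %in% names(df)) stop_ctx("bird table needs an 'id' column")
  df$id <- as.character(df$id)
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) stop_ctx("duplicated bird id(s): ", paste(dup, collapse = ", "))

  check_enum <- function(col, allowed) {
    if (!col %in% names(df)) return(invisible())
    bad <- setdiff(stats::na.omit(unique(df[[col]])), allowed)
    if (length(bad))
      stop_ctx("unknown ", col, " token(s): ", paste(bad, collapse = ", "))
  }
  check_enum("source", c("bycatch", "reference_ys", "reference_bs"))
  check_enum("sex", c("male", "female", "unknown"))
  check_enum("plumage_call", c("YS", "BS", "doubtful", "missing"))
  check_enum("true_species", species_levels())

  num_cols <- intersect(c(biometric_names(), isotope_names()), names(df))
  for (col in num_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (any(!is.na(v) & is.na(vn)))
        stop_ctx("non-numeric values in measurement column '", col, "'")
      df[[col]] <- vn
    }
  }
  for (col in intersect(biometric_names(), names(df)))
    if (any(df[[col]] <= 0, na.rm = TRUE))
      stop_ctx("non-positive biometric values in '", col, "'")
  for (col in intersect(c("d15N_P1", "d15N_R6"), names(df)))
    if (any(df[[col]] <= 0 | df[[col]] >= 30, na.rm = TRUE))
      stop_ctx("delta15N outside (0, 30) in '", col, "'")
  for (col in intersect(c("d13C_P1", "d13C_R6"), names(df)))
    if (any(df[[col]] >= 0 | df[[col]] <= -30, na.rm = TRUE))
      stop_ctx("delta13C outside (-30, 0) in '", col, "'")

  if (all(c("source", "true_species") %in% names(df))) {
    ref <- grepl("^reference_", df$source)
    if (any(ref & is.na(df$true_species)))
      stop_ctx("reference birds must carry a definite species label")
  }
  class(df) <- c("bird_table", "data.frame")
  df
}

#' Read an aligned FASTA file
#'
#' Reads a multiple sequence alignment (e.g. the 293-bp mtDNA control-region
#' Domain I fragment). All rows must have equal length; sequences are
#' uppercased. Gaps (`-`) and IUPAC ambiguity codes are retained and handled
#' downstream by [identity_distance()].
#'
#' @param path FASTA file with at least two records.
#' @return A named character vector of equal-length sequences, class
#'   `alignment`.
#' @export
read_fasta_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L) stop_ctx("alignment needs >= 2 sequences")
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  as_alignment(seqs)
}

#' Write an alignment to FASTA
#' @param aln Named character vector of equal-length sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(unclass(aln))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

as_alignment <- function(seqs) {
  lens <- nchar(seqs)
  if (length(seqs) == 0L || lens[1] == 0L) stop_ctx("empty alignment")
  if (length(unique(lens)) != 1L)
    stop_ctx("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop_ctx("alignment sequence ids must be unique and non-empty")
  structure(seqs, class = "alignment")
}

#' Read landmark configurations from a TPS file
#'
#' Parses the tpsDig dialect: per specimen a `LM=n` line, `n` whitespace-
#' separated coordinate pairs, and optional `IMAGE=`, `ID=` and `SCALE=`
#' lines. Raw (pixel) coordinates are multiplied by `SCALE` when present so
#' that returned coordinates are in absolute units (mm).
#'
#' @param path TPS file path.
#' @param n_points Expected number of points per configuration (default 13:
#'   10 landmarks + 3 semilandmarks); `NULL` disables the check.
#' @return A list of landmark configurations (see [landmark_config()]).
#' @export
read_tps <- function(path, n_points = 13L) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (!length(starts)) stop_ctx("no LM= records in TPS file")
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:ends[i]]
    n <- as.integer(sub("^LM\\s*=\\s*", "", block[1], ignore.case = TRUE))
    coord_lines <- grep("^[-+0-9.eE]+\\s+[-+0-9.eE]+$", block[-1], value = TRUE)
    if (length(coord_lines) != n)
      stop_ctx("TPS record ", i, ": LM=", n, " but ", length(coord_lines),
               " coordinate pairs")
    xy <- do.call(rbind, lapply(strsplit(coord_lines, "\\s+"), as.numeric))
    if (anyNA(xy)) stop_ctx("TPS record ", i, ": non-numeric coordinates")
    get_tag <- function(tag) {
      m <- grep(paste0("^", tag, "\\s*="), block, ignore.case = TRUE, value = TRUE)
      if (length(m)) sub(paste0("^", tag, "\\s*=\\s*"), "", m[1], ignore.case = TRUE)
      else NULL
    }
    scale <- get_tag("SCALE")
    if (!is.null(scale)) xy <- xy * as.numeric(scale)
    id <- get_tag("ID") %||% as.character(i)
    if (!is.null(n_points) && n != n_points)
      stop_ctx("TPS record ", i, ": expected ", n_points, " points, got ", n)
    out[[i]] <- landmark_config(xy, id = id)
  }
  out
}

#' Write landmark configurations to a TPS file
#'
#' Coordinates are written as-is with `SCALE=1.0` (already in absolute
#' units), so [read_tps()] round-trips exactly.
#'
#' @param configs List of landmark configurations.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in configs) {
    writeLines(sprintf("LM=%d", nrow(cf$points)), con)
    writeLines(sprintf("%.10g %.10g", cf$points[, 1], cf$points[, 2]), con)
    writeLines(sprintf("ID=%s", cf$id), con)
    writeLines("SCALE=1.0", con)
  }
  invisible(path)
}

#' Construct a landmark configuration
#'
#' A 2-D configuration of bill landmarks: by default 10 fixed landmarks plus
#' 3 semilandmarks (points 11--13) that slide along the outline of the
#' superior unguicorn between landmarks 1 and 10 (curve order
#' 1, 11, 12, 13, 10).
#'
#' @param points Numeric k x 2 matrix of coordinates (mm).
#' @param id Specimen identifier.
#' @param roles Character vector `"fixed"`/`"semilandmark"` per point;
#'   default tags points 11--13 as semilandmarks when k = 13, otherwise all
#'   fixed.
#' @param curve_order Indices of the outline the semilandmarks slide on.
#' @return A list with elements `id`, `points`, `roles`, `curve_order`, of
#'   class `landmark_config`.
#' @export
landmark_config <- function(points, id = "lm", roles = NULL, curve_order = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop_ctx("landmark configuration must be k x 2")
  if (!all(is.finite(points))) stop_ctx("non-finite landmark coordinates")
  if (nrow(points) < 3L) stop_ctx("need >= 3 landmarks")
  if (is.null(roles)) {
    roles <- rep("fixed", nrow(points))
    if (nrow(points) == 13L) roles[11:13] <- "semilandmark"
  }
  if (is.null(curve_order) && any(roles == "semilandmark")) {
    if (nrow(points) == 13L) curve_order <- c(1L, 11L, 12L, 13L, 10L)
    else stop_ctx("curve_order required when semilandmarks are present")
  }
  semis <- which(roles == "semilandmark")
  if (length(semis) && !all(semis %in% curve_order))
    stop_ctx("all semilandmarks must appear in curve_order")
  structure(list(id = as.character(id), points = unname(points),
                 roles = roles, curve_order = curve_order),
            class = "landmark_config")
}

#' Assign a feather moult year from the collection date
#'
#' Flight feathers of the study species are renewed between May and October,
#' so birds collected in March--June carry feathers grown the previous
#' calendar year, while birds collected in October--November carry
#' same-year feathers. Dates in other months cannot be resolved and return
#' `NA` (such birds are excluded from the temporal analyses).
#'
#' @param collection_date `Date` vector (or ISO-8601 strings).
#' @return Integer vector of moult years, `NA` where unresolvable.
#' @export
assign_moult_year <- function(collection_date) {
  d <- as.Date(collection_date)
  mo <- as.integer(format(d, "%m"))
  yr <- as.integer(format(d, "%Y"))
  out <- rep(NA_integer_, length(d))
  out[mo %in% 3:6] <- yr[mo %in% 3:6] - 1L
  out[mo %in% 10:11] <- yr[mo %in% 10:11]
  out
}
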