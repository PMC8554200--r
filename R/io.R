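# TSV interchange with '#' header comments; numbers are written with full
# precision ("%.17g") so a write/read round trip reproduces values exactly.

fmt_num <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  sub("^(-?\\d+)\\.0*$", "\\1", out)
}

# lightweight provenance hash (stamped into output headers)
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE)
  b <- as.integer(charToRaw(s))
  sprintf("%08x", sum(b * (seq_along(b) %% 97 + 1)) %% .Machine$integer.max)
}

header_lines <- function(meta) {
  meta <- c(list(version = as.character(utils::packageVersion("hlvqtl"))), meta)
  paste0("# ", names(meta), "=", vapply(meta, as.character, character(1)))
}

#' Write a data frame as TSV with a provenance header
#'
#' @param df Data frame.
#' @param path Output path.
#' @param meta Named list stamped into `#`-prefixed header comment lines
#'   (e.g. seed, config hash).
#' @return `path`, invisibly.
#' @export
write_hlv_tsv <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header_lines(meta), con)
  df2 <- df
  for (j in seq_along(df2))
    if (is.double(df2[[j]])) df2[[j]] <- fmt_num(df2[[j]])
  write.table(df2, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_hlv_tsv()]
#'
#' @param path Input path.
#' @return A data frame; header metadata in `attr(, "meta")`.
#' @export
read_hlv_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  if (length(hdr)) {
    kv <- sub("^# *", "", lines[hdr])
    parts <- strsplit(kv, "=", fixed = TRUE)
    meta <- setNames(lapply(parts, function(p) paste(p[-1], collapse = "=")),
                     vapply(parts, `[`, "", 1))
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

phenotypes_long <- function(ds) {
  T <- length(ds$times)
  rows <- list()
  add <- function(ids, Y, condition, species) {
    data.frame(pair_id = rep(ids, each = T),
               condition = condition, species = species,
               time = rep(ds$times, length(ids)),
               abundance = as.vector(t(Y)), stringsAsFactors = FALSE)
  }
  pid <- ds$pairing$pair_id
  rows$coE <- add(pid, ds$Y_cc[, 1:T, drop = FALSE], "co", "A")
  rows$coS <- add(pid, ds$Y_cc[, (T + 1):(2 * T), drop = FALSE], "co", "B")
  if (!is.null(ds$Y_mono_A)) rows$moA <- add(pid, ds$Y_mono_A, "mono", "A")
  if (!is.null(ds$Y_mono_B)) rows$moB <- add(pid, ds$Y_mono_B, "mono", "B")
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

genotypes_df <- function(G) {
  data.frame(strain = rownames(G), as.data.frame(G, optional = TRUE),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a community dataset to a directory
#'
#' Writes `genotypes_A.tsv`, `genotypes_B.tsv` (strains x markers, 0/1),
#' `phenotypes.tsv` (`pair_id`, `condition`, `species`, `time`,
#' `abundance`), `pairing.tsv` and, for simulated data, `truth.json`.
#' Every TSV carries `#` header comments recording the package version and
#' any supplied metadata (seed, config hash).
#'
#' @param dataset A `community_dataset`.
#' @param dir Output directory (created if needed).
#' @param meta Named list of provenance values for the headers.
#' @return `dir`, invisibly.
#' @export
write_community_dataset <- function(dataset, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(dataset$truth$seed) && is.null(meta$seed))
    meta$seed <- dataset$truth$seed
  write_hlv_tsv(genotypes_df(dataset$genotypes_A),
                file.path(dir, "genotypes_A.tsv"), meta)
  write_hlv_tsv(genotypes_df(dataset$genotypes_B),
                file.path(dir, "genotypes_B.tsv"), meta)
  write_hlv_tsv(dataset$pairing, file.path(dir, "pairing.tsv"), meta)
  write_hlv_tsv(phenotypes_long(dataset), file.path(dir, "phenotypes.tsv"), meta)
  if (!is.null(dataset$truth)) {
    tr <- dataset$truth
    tr$theta <- apply(tr$theta, 1, as.list, simplify = FALSE)
    writeLines(jsonlite::toJSON(tr, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(dir, "truth.json"))
  }
  invisible(dir)
}

stop_at <- function(path, line, msg)
  stop(basename(path), " line ", line, ": ", msg, call. = FALSE)

read_genotype_file <- function(path) {
  df <- read_hlv_tsv(path)
  if (names(df)[1] != "strain") stop_at(path, 1, "first column must be 'strain'")
  G <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(G) || !all(G %in% c(0, 1)))
    stop(basename(path), ": genotypes must be 0/1")
  rownames(G) <- df$strain
  G
}

#' Read a community dataset from a directory
#'
#' Reads the files written by [write_community_dataset()], enforcing
#' cross-file consistency: every phenotype row must reference a known pair,
#' every pairing row must resolve to strains present in the genotype
#' matrices, and (pair, condition, species, time) keys must be unique.
#' Violations raise an error naming the file and line.
#'
#' @param dir Directory containing the dataset files.
#' @return A `community_dataset`.
#' @export
read_community_dataset <- function(dir) {
  paths <- file.path(dir, c("genotypes_A.tsv", "genotypes_B.tsv",
                            "pairing.tsv", "phenotypes.tsv"))
  for (p in paths) if (!file.exists(p)) stop("missing input file: ", p)
  GA <- read_genotype_file(paths[1])
  GB <- read_genotype_file(paths[2])
  pairing <- read_hlv_tsv(paths[3])
  attr(pairing, "meta") <- NULL
  need <- c("pair_id", "strain_A", "strain_B")
  if (!all(need %in% names(pairing)))
    stop("pairing.tsv: missing column(s): ",
         paste(setdiff(need, names(pairing)), collapse = ", "))
  miss_A <- !pairing$strain_A %in% rownames(GA)
  if (any(miss_A))
    stop_at(paths[3], which(miss_A)[1], paste0("unknown strain id '",
            pairing$strain_A[which(miss_A)[1]], "' in genotypes_A"))
  miss_B <- !pairing$strain_B %in% rownames(GB)
  if (any(miss_B))
    stop_at(paths[3], which(miss_B)[1], paste0("unknown strain id '",
            pairing$strain_B[which(miss_B)[1]], "' in genotypes_B"))

  ph_path <- paths[4]
  lines <- readLines(ph_path)
  n_comment <- sum(grepl("^#", lines))
  ph <- read_hlv_tsv(ph_path)
  need <- c("pair_id", "condition", "species", "time", "abundance")
  if (!all(need %in% names(ph)))
    stop("phenotypes.tsv: missing column(s): ",
         paste(setdiff(need, names(ph)), collapse = ", "))
  line_of <- function(i) i + n_comment + 1L  # + header row
  bad <- !ph$pair_id %in% pairing$pair_id
  if (any(bad))
    stop_at(ph_path, line_of(which(bad)[1]),
            paste0("unknown pair id '", ph$pair_id[which(bad)[1]], "'"))
  if (!is.numeric(ph$abundance)) {
    suppressWarnings(num <- as.numeric(ph$abundance))
    stop_at(ph_path, line_of(which(is.na(num))[1]), "non-numeric abundance")
  }
  if (any(!is.finite(ph$abundance)))
    stop_at(ph_path, line_of(which(!is.finite(ph$abundance))[1]),
            "non-finite abundance")
  key <- paste(ph$pair_id, ph$condition, ph$species, ph$time)
  dup <- duplicated(key)
  if (any(dup))
    stop_at(ph_path, line_of(which(dup)[1]),
            "duplicated (pair, condition, species, time) observation")

  times <- sort(unique(ph$time))
  T <- length(times)
  to_matrix <- function(sub, ids) {
    m <- matrix(NA_real_, length(ids), T, dimnames = list(ids, NULL))
    idx_r <- match(sub$pair_id, pairing$pair_id)
    idx_c <- match(sub$time, times)
    m[cbind(idx_r, idx_c)] <- sub$abundance
    if (any(is.na(m))) stop("phenotypes.tsv: incomplete time grid for some pairs")
    m
  }
  coE <- ph[ph$condition == "co" & ph$species == "A", ]
  coS <- ph[ph$condition == "co" & ph$species == "B", ]
  if (!nrow(coE) || !nrow(coS)) stop("phenotypes.tsv: no co-culture observations")
  Y <- cbind(to_matrix(coE, pairing$pair_id), to_matrix(coS, pairing$pair_id))
  colnames(Y) <- c(sprintf("E_t%02d", seq_len(T)), sprintf("S_t%02d", seq_len(T)))
  ds <- list(genotypes_A = GA, genotypes_B = GB, pairing = pairing,
             times = times, Y_cc = Y)
  moA <- ph[ph$condition == "mono" & ph$species == "A", ]
  if (nrow(moA)) {
    YA <- to_matrix(moA, pairing$pair_id)
    dimnames(YA) <- list(pairing$strain_A, sprintf("t%02d", seq_len(T)))
    ds$Y_mono_A <- YA
  }
  moB <- ph[ph$condition == "mono" & ph$species == "B", ]
  if (nrow(moB)) {
    YB <- to_matrix(moB, pairing$pair_id)
    dimnames(YB) <- list(pairing$strain_B, sprintf("t%02d", seq_len(T)))
    ds$Y_mono_B <- YB
  }
  tpath <- file.path(dir, "truth.json")
  if (file.exists(tpath)) {
    tr <- jsonlite::fromJSON(tpath, simplifyVector = TRUE)
    if (!is.null(tr$theta))
      tr$theta <- do.call(rbind, lapply(tr$theta, function(x)
        unlist(x)[theta_names()]))
    ds$truth <- tr
  }
  structure(ds, class = "community_dataset")
}

#' Write scan results as TSV
#'
#' One row per tested unit with LR, threshold, significance and flattened
#' per-combination estimates; skipped units (and reasons) go to a sidecar
#' `<path>.skipped.log`.
#'
#' @param scan An `hlv_scan` data frame.
#' @param path Output TSV path.
#' @param meta Provenance metadata for the header.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path, meta = list()) {
  write_hlv_tsv(as.data.frame(scan), path, meta)
  skipped <- attr(scan, "skipped")
  if (!is.null(skipped) && nrow(skipped))
    write_hlv_tsv(skipped, paste0(path, ".skipped.log"), meta)
  invisible(path)
}

#' Write a trajectory as TSV
#'
#' @param trajectory Data frame with columns `time`, `E`, `S` (from
#'   [solve_hlv()]).
#' @param path Output path.
#' @param meta Provenance metadata.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(trajectory, path, meta = list())
  write_hlv_tsv(trajectory, path, meta)
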