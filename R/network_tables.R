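# Zone (SOZ) and region network labeling of channel pairs, and assembly of
# the long-format pair table feeding the statistics stage.

#' Zone-pair label for a channel pair
#'
#' "inside" when both contacts are in the seizure-onset zone, "outside" when
#' neither is, "between" otherwise. Symmetric in its arguments.
#'
#' @param soz_a,soz_b SOZ flags (0/1 or logical) of the two contacts.
#' @return one of "inside", "outside", "between".
#' @export
zone_pair_label <- function(soz_a, soz_b) {
  if (is.na(soz_a) || is.na(soz_b)) stop("missing SOZ flag")
  a <- as.logical(soz_a); b <- as.logical(soz_b)
  if (a && b) "inside" else if (!a && !b) "outside" else "between"
}

#' Region-pair (network) label for a channel pair
#'
#' Contacts are classed mesial temporal (M), lateral temporal (L) or
#' extratemporal (E); the six networks are M-M, M-L, M-E, L-L, L-E, E-E,
#' canonically ordered M < L < E and symmetric in the arguments.
#'
#' @param region_a,region_b region codes of the two contacts.
#' @return the canonical network label, e.g. "M-L".
#' @export
region_pair_label <- function(region_a, region_b) {
  lev <- c("M", "L", "E")
  if (!(region_a %in% lev) || !(region_b %in% lev))
    stop("unknown region code: ", region_a, "/", region_b)
  r <- lev[sort(match(c(region_a, region_b), lev))]
  paste(r, collapse = "-")
}

#' Assemble the long-format channel-pair table
#'
#' One record per unordered channel pair, combining per-band connectivity,
#' the spike-coupling rate, inter-contact distance, zone- and region-network
#' labels, patient id and surgical outcome. Ipsilateral and contralateral
#' NSOZ contacts are pooled by default; with `hemisphere_split = TRUE` a
#' `laterality` column ("ipsi"/"contra") is added.
#'
#' @param conn named list of `connectivity_matrix` objects (one per band,
#'   e.g. `theta`, `low_gamma`, `high_gamma`), all over the same channels.
#' @param spikes a `spike_coupling_matrix` over the same channels.
#' @param distances labeled distance matrix from [distance_matrix()].
#' @param meta channel metadata (label, region, soz, hemisphere, ...).
#' @param patient_id patient identifier.
#' @param outcome surgical outcome, "SF" (seizure free) or "NSF".
#' @param hemisphere_split add the laterality annotation (default FALSE).
#' @return a tibble with `Nc * (Nc - 1) / 2` rows and columns `patient`,
#'   `channel_i`, `channel_j`, one `h_<band>` per supplied band,
#'   `spike_rate`, `distance_mm`, `zone_pair`, `region_pair`, `outcome`.
#' @export
build_pair_table <- function(conn, spikes, distances, meta, patient_id,
                             outcome = c("SF", "NSF"),
                             hemisphere_split = FALSE) {
  outcome <- match.arg(outcome)
  channels <- conn[[1]]$channels
  for (cm in conn)
    if (!identical(cm$channels, channels))
      stop("connectivity matrices cover different channel sets")
  if (!identical(rownames(spikes$r), channels) ||
      !identical(rownames(distances), channels))
    stop("channel-set mismatch between connectivity, spikes and distances")
  meta <- meta[match(channels, meta$label), ]
  if (anyNA(meta$label)) stop("metadata missing analyzed channel(s)")

  nc <- length(channels)
  ii <- jj <- integer(0)
  for (i in seq_len(nc - 1)) {
    ii <- c(ii, rep(i, nc - i))
    jj <- c(jj, (i + 1):nc)
  }
  out <- tibble::tibble(
    patient = patient_id,
    channel_i = channels[ii],
    channel_j = channels[jj]
  )
  for (bn in names(conn)) out[[paste0("h_", bn)]] <- conn[[bn]]$h[cbind(ii, jj)]
  out$spike_rate <- spikes$r[cbind(ii, jj)]
  out$distance_mm <- distances[cbind(ii, jj)]
  out$zone_pair <- mapply(zone_pair_label, meta$soz[ii], meta$soz[jj],
                          USE.NAMES = FALSE)
  out$region_pair <- mapply(region_pair_label, meta$region[ii],
                            meta$region[jj], USE.NAMES = FALSE)
  if (hemisphere_split)
    out$laterality <- ifelse(meta$hemisphere[ii] == meta$hemisphere[jj],
                             "ipsi", "contra")
  out$outcome <- outcome
  out
}

#' Write / read a pair table as TSV
#'
#' The TSV with this fixed column layout is the statistics-stage input
#' contract.
#'
#' @param table a pair table from [build_pair_table()] (rows from several
#'   patients may be bound together).
#' @param path file path.
#' @return `path` (write) or the tibble (read).
#' @export
write_pair_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Write a labeled symmetric matrix as TSV
#' @param m matrix with dimnames (connectivity, distance or spike-rate).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(m, path) {
  utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
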