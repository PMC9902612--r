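#' Assign ACC bursts backward to GPS fixes
#'
#' Every burst with timestamp in the half-open interval [fix_k, fix_{k+1})
#' attaches to fix_k (a burst exactly at a fix timestamp attaches to that
#' fix). When the next fix is missing, bursts attach to the previous fix
#' only if within `maxGapMin` minutes of it (default 60); later bursts are
#' dropped until the next fix. Bursts before an individual's first fix are
#' dropped.
#'
#' @param fixes fix table (individual_id, timestamp, ...), sorted by
#'   timestamp within individual.
#' @param bursts burst table (individual_id, timestamp, behavior_label, ...),
#'   sorted by timestamp within individual.
#' @param maxGapMin backward-assignment cutoff in minutes (default 60).
#' @return `bursts` with an added POSIXct column `fix_timestamp` (`NA` for
#'   dropped bursts).
#' @export
assignBursts <- function(fixes, bursts, maxGapMin = 60) {
  .checkSorted(fixes, "fixes"); .checkSorted(bursts, "bursts")
  out <- bursts
  out$fix_timestamp <- as.POSIXct(rep(NA_real_, nrow(bursts)),
                                  origin = "1970-01-01", tz = "UTC")
  for (id in unique(bursts$individual_id)) {
    ft <- fixes$timestamp[fixes$individual_id == id]
    bi <- which(bursts$individual_id == id)
    if (length(ft) == 0L || length(bi) == 0L) next
    bt <- bursts$timestamp[bi]
    k <- findInterval(as.numeric(bt), as.numeric(ft))
    nxt <- c(as.numeric(ft), Inf)[k + 1L]
    prev <- as.numeric(ft)[pmax(k, 1L)]
    ok <- k >= 1L & as.numeric(bt) < nxt &
      (as.numeric(bt) - prev) <= maxGapMin * 60
    out$fix_timestamp[bi[ok]] <- ft[k[ok]]
  }
  out
}

.checkSorted <- function(tab, what) {
  stopifnot(all(c("individual_id", "timestamp") %in% names(tab)))
  bad <- vapply(split(as.numeric(tab$timestamp), tab$individual_id),
                is.unsorted, TRUE)
  if (any(bad)) stop(what, " must be sorted by timestamp within individual")
  invisible(TRUE)
}

#' Split fix series into regular sequences
#'
#' A new sequence starts whenever the gap to the previous retained fix
#' strictly exceeds `maxGapMin` minutes (default 120, i.e. 4 missing 30-min
#' fixes); a gap of exactly 120 min stays in the same sequence. Transitions
#' are later formed only within a sequence.
#'
#' @param fixes fix table sorted by timestamp within individual.
#' @param maxGapMin gap threshold in minutes (default 120; strict `>`).
#' @return `fixes` with an added character column `sequence_id`.
#' @export
segmentSequences <- function(fixes, maxGapMin = 120) {
  .checkSorted(fixes, "fixes")
  seqId <- character(nrow(fixes))
  for (id in unique(fixes$individual_id)) {
    idx <- which(fixes$individual_id == id)
    gaps <- diff(as.numeric(fixes$timestamp[idx])) / 60
    newSeq <- c(TRUE, gaps > maxGapMin)
    seqId[idx] <- sprintf("%s_seq%03d", id, cumsum(newSeq))
  }
  fixes$sequence_id <- seqId
  fixes
}

#' Behavior proportions per fix interval
#'
#' Counts the assigned bursts of each fix and converts label counts to
#' proportions over (forage, walk, stationary, flight). Only forage, walk
#' and stationary later enter the design (flight is excluded to avoid the
#' proportions-sum-to-one collinearity); fixes with no assigned bursts get
#' no row and thus drop out of the model data.
#'
#' @param assigned burst table with `fix_timestamp` from [assignBursts()];
#'   every assigned burst must carry a label in [BEHAVIORS].
#' @return data.frame: individual_id, timestamp, n_bursts, p_forage,
#'   p_walk, p_stationary, p_flight.
#' @export
behaviorProportions <- function(assigned) {
  stopifnot(all(c("individual_id", "fix_timestamp", "behavior_label")
                %in% names(assigned)))
  keep <- !is.na(assigned$fix_timestamp)
  a <- assigned[keep, , drop = FALSE]
  if (anyNA(a$behavior_label) || !all(a$behavior_label %in% BEHAVIORS))
    stop("assigned bursts must be labeled with one of: ",
         paste(BEHAVIORS, collapse = ", "))
  if (nrow(a) == 0L)
    return(data.frame(individual_id = character(), timestamp = as.POSIXct(character()),
                      n_bursts = integer(), p_forage = numeric(),
                      p_walk = numeric(), p_stationary = numeric(),
                      p_flight = numeric()))
  key <- paste(a$individual_id, as.numeric(a$fix_timestamp))
  grp <- split(seq_len(nrow(a)), key)
  rows <- lapply(grp, function(idx) {
    n <- length(idx)
    cnt <- tabulate(match(a$behavior_label[idx], BEHAVIORS), 4L)
    data.frame(individual_id = a$individual_id[idx[1]],
               timestamp = a$fix_timestamp[idx[1]],
               n_bursts = n,
               p_forage = cnt[1] / n, p_walk = cnt[2] / n,
               p_stationary = cnt[3] / n, p_flight = cnt[4] / n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$individual_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Harmonic time-of-day covariates
#'
#' cos_diel = cos(2 pi h / 24) and sin_time = sin(2 pi h / 24) with h the
#' fractional local hour: cos_diel is positive at night and negative at
#' midday; sin_time is positive from midnight to 11:59 a.m. and negative
#' from noon onward. Timestamps are assumed to already be in local time.
#'
#' @param timestamps POSIXct vector.
#' @return data.frame with columns cos_diel, sin_time (both in [-1, 1]).
#' @export
timeCovariates <- function(timestamps) {
  lt <- as.POSIXlt(timestamps)
  h <- lt$hour + lt$min / 60 + lt$sec / 3600
  data.frame(cos_diel = cos(2 * pi * h / 24), sin_time = sin(2 * pi * h / 24))
}

#' Center and scale model covariates
#'
#' Transforms forage, walk, stationary and temperature to mean 0 / sd 1
#' (sample sd, n-1 denominator) using dataset-wide moments, computed from
#' `records` when `spec` is NULL and applied from `spec` otherwise (so a fit
#' scale can be reused, e.g. the generating scale of a simulation). Harmonic
#' time covariates are left untouched.
#'
#' @param records transition-record data.frame.
#' @param spec optional standardization data.frame (covariate, mean, sd).
#' @return list: `records` (standardized) and `spec` (the moments used).
#' @export
standardizeRecords <- function(records, spec = NULL) {
  covs <- c("forage", "walk", "stationary", "temperature")
  stopifnot(all(covs %in% names(records)))
  if (any(!is.finite(as.matrix(records[, covs]))))
    stop("covariates must be finite")
  if (is.null(spec)) {
    mu <- vapply(records[covs], mean, 0)
    sdv <- vapply(records[covs], stats::sd, 0)
    if (any(sdv == 0))
      stop("zero-variance covariate: ", paste(covs[sdv == 0], collapse = ", "))
    spec <- data.frame(covariate = covs, mean = unname(mu), sd = unname(sdv),
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(covs %in% spec$covariate), all(spec$sd > 0))
  for (k in covs) {
    row <- match(k, spec$covariate)
    records[[k]] <- (records[[k]] - spec$mean[row]) / spec$sd[row]
  }
  list(records = records, spec = spec)
}

#' Build transition records from fixes and behavior intervals
#'
#' Emits one record per pair of consecutive fixes within a sequence that are
#' exactly one fix period apart (a single missing fix breaks the pair; no
#' transition bridges the gap). The record carries the origin fix's habitat
#' as `from`, the next fix's habitat as `to` (self-transitions allowed),
#' and the origin fix's behavior proportions, temperature and harmonic
#' clock covariates. Origin fixes with no behavior interval (no assigned
#' bursts) produce no record.
#'
#' @param fixes fix table with `sequence_id` (see [segmentSequences()]) and
#'   columns habitat, region, temperature_c.
#' @param intervals output of [behaviorProportions()].
#' @param fixPeriodMin fix period in minutes (default 30).
#' @return data.frame: individual_id, sequence_id, t, from, to, region,
#'   cos_diel, sin_time, forage, walk, stationary, temperature (raw scale;
#'   see [standardizeRecords()]).
#' @export
buildTransitionRecords <- function(fixes, intervals, fixPeriodMin = 30) {
  stopifnot("sequence_id" %in% names(fixes))
  key <- paste(fixes$individual_id, as.numeric(fixes$timestamp))
  ikey <- paste(intervals$individual_id, as.numeric(intervals$timestamp))
  im <- match(key, ikey)
  n <- nrow(fixes)
  if (n < 2L) return(.emptyRecords())
  sameSeq <- fixes$sequence_id[-n] == fixes$sequence_id[-1] &
    fixes$individual_id[-n] == fixes$individual_id[-1]
  oneStep <- diff(as.numeric(fixes$timestamp)) == fixPeriodMin * 60
  hasInt <- !is.na(im[-n])
  use <- which(sameSeq & oneStep & hasInt)
  if (length(use) == 0L) return(.emptyRecords())
  tc <- timeCovariates(fixes$timestamp[use])
  iv <- intervals[im[use], ]
  out <- data.frame(
    individual_id = fixes$individual_id[use],
    sequence_id = fixes$sequence_id[use],
    t = stats::ave(seq_along(use), fixes$sequence_id[use], FUN = seq_along),
    from = fixes$habitat[use],
    to = fixes$habitat[use + 1L],
    region = fixes$region[use],
    cos_diel = tc$cos_diel,
    sin_time = tc$sin_time,
    forage = iv$p_forage,
    walk = iv$p_walk,
    stationary = iv$p_stationary,
    temperature = fixes$temperature_c[use],
    stringsAsFactors = FALSE)
  out <- out[order(out$individual_id, out$sequence_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyRecords <- function() {
  data.frame(individual_id = character(), sequence_id = character(),
             t = integer(), from = character(), to = character(),
             region = character(), cos_diel = numeric(), sin_time = numeric(),
             forage = numeric(), walk = numeric(), stationary = numeric(),
             temperature = numeric(), stringsAsFactors = FALSE)
}

#' Structural-zero mask from observed transitions
#'
#' A (region, from, to) cell is allowed iff both habitats are available in
#' the region, and either the destination is the baseline habitat or the
#' (from -> to) transition is observed at least once — within that region
#' (`scope = "region"`, default) or anywhere in the dataset
#' (`scope = "global"`). All remaining cells are structural zeros whose
#' transition probability is fixed at exactly 0. Errors if any record's own
#' transition would be masked (inconsistent inputs).
#'
#' @param records transition-record data.frame.
#' @param regionHabitats named list region -> available habitats.
#' @param baseline baseline habitat label (always allowed where available).
#' @param habitats,regions full label sets; default from `regionHabitats`
#'   and the records.
#' @param scope "region" or "global" observation criterion.
#' @return logical array region x from x to.
#' @export
structuralMask <- function(records, regionHabitats, baseline,
                           habitats = NULL, regions = names(regionHabitats),
                           scope = c("region", "global")) {
  scope <- match.arg(scope)
  if (nrow(records) == 0L) stop("records must be non-empty")
  if (is.null(habitats))
    habitats <- sort(unique(unlist(regionHabitats)))
  mask <- availabilityMask(regionHabitats, habitats, regions)
  H <- length(habitats)
  ri <- match(records$region, regions)
  fi <- match(records$from, habitats)
  ti <- match(records$to, habitats)
  if (anyNA(ri) || anyNA(fi) || anyNA(ti))
    stop("records contain labels outside the supplied habitat/region sets")
  obsGlobal <- matrix(FALSE, H, H)
  obsGlobal[cbind(fi, ti)] <- TRUE
  jb <- match(baseline, habitats)
  if (is.na(jb)) stop("baseline must be one of the habitats")
  for (r in seq_along(regions)) {
    if (scope == "region") {
      obs <- matrix(FALSE, H, H)
      sel <- ri == r
      obs[cbind(fi[sel], ti[sel])] <- TRUE
    } else obs <- obsGlobal
    obs[, jb] <- TRUE  # baseline destination always allowed where available
    mask[r, , ] <- mask[r, , ] & obs
  }
  bad <- !mask[cbind(ri, fi, ti)]
  if (any(bad))
    stop("record(s) whose own (region, from, to) would be masked: ",
         paste(unique(sprintf("%s|%s|%s", records$region[bad],
                              records$from[bad], records$to[bad])),
               collapse = "; "))
  mask
}

#' Full preprocessing pipeline
#'
#' Chains burst assignment, behavior proportions, sequence segmentation,
#' record construction, covariate standardization and structural-zero
#' masking.
#'
#' @param fixes,bursts input tables (schemas of [simulateTracks()] /
#'   [simulateBursts()]).
#' @param baseline baseline habitat label.
#' @param regionHabitats named list region -> available habitats; derived
#'   from the habitats observed per region when NULL.
#' @param habitats,regions label sets; derived from the fixes when NULL.
#' @param standardization optional standardization spec to apply instead of
#'   fitting dataset moments.
#' @param scope structural-zero observation scope ("region" or "global").
#' @param fixPeriodMin,assignMaxGapMin,segmentMaxGapMin preprocessing
#'   constants in minutes (defaults 30, 60, 120).
#' @return list: `records` (standardized), `standardization`, `mask`,
#'   `intervals`.
#' @export
preprocessTracks <- function(fixes, bursts, baseline = defaultBaseline(),
                             regionHabitats = NULL, habitats = NULL,
                             regions = NULL, standardization = NULL,
                             scope = c("region", "global"),
                             fixPeriodMin = 30, assignMaxGapMin = 60,
                             segmentMaxGapMin = 120) {
  scope <- match.arg(scope)
  if (is.null(habitats)) habitats <- sort(unique(fixes$habitat))
  if (is.null(regions)) regions <- sort(unique(fixes$region))
  if (is.null(regionHabitats))
    regionHabitats <- lapply(stats::setNames(regions, regions), function(r)
      sort(unique(fixes$habitat[fixes$region == r])))
  assigned <- assignBursts(fixes, bursts, maxGapMin = assignMaxGapMin)
  intervals <- behaviorProportions(assigned)
  fixes <- segmentSequences(fixes, maxGapMin = segmentMaxGapMin)
  records <- buildTransitionRecords(fixes, intervals, fixPeriodMin = fixPeriodMin)
  std <- standardizeRecords(records, spec = standardization)
  mask <- structuralMask(std$records, regionHabitats, baseline,
                         habitats = habitats, regions = regions, scope = scope)
  list(records = std$records, standardization = std$spec, mask = mask,
       intervals = intervals)
}
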