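# Data model and I/O for bilateral capture histories with partial identity.
#
# File conventions (all CSV, UTF-8, one event per row):
#   traps.csv:      trap_id,x,y
#   captures.csv:   individual_id,detector,trap_id,occasion,simultaneous
#   identities.csv: detector1_id,detector2_id   (optional explicit links)
# Files use 1-based trap/occasion ids; internal arrays are plain R arrays
# indexed from 1 as usual.

#' Summarize one individual's bilateral history
#'
#' Computes the counts that drive the bilateral likelihoods: per-detector
#' totals, the combined total, and for each trap the number of occasions with
#' at least one detection on either detector as well as the combined per-trap
#' totals.
#'
#' @param y1Row,y2Row binary J x K matrices (detector 1 and the detector-2 row
#'   aligned to the same individual).
#' @return a [SummaryCounts-class].
#' @examples
#' y1 <- matrix(0, 2, 3); y2 <- matrix(0, 2, 3)
#' y1[1, 2] <- 1; y2[1, 2] <- 1  # one simultaneous capture
#' summarizeIndividual(y1, y2)@yDotDot  # 2
#' @export
summarizeIndividual <- function(y1Row, y2Row) {
  y1Row <- as.matrix(y1Row); y2Row <- as.matrix(y2Row)
  if (!all(dim(y1Row) == dim(y2Row)))
    stop("detector-1 and detector-2 rows must have identical J x K shape")
  y1Total <- sum(y1Row)
  y2Total <- sum(y2Row)
  nij <- rowSums((y1Row + y2Row) > 0)
  new("SummaryCounts",
      y1Total = y1Total, y2Total = y2Total, yDotDot = y1Total + y2Total,
      nij = as.numeric(nij), nDot = sum(nij),
      yijDot = as.numeric(rowSums(y1Row) + rowSums(y2Row)))
}

#' Derive known identity links from verified simultaneous captures
#'
#' A detector-1 row and a detector-2 row are linked (full identity) only when
#' metadata confirm at least one simultaneous capture: both detectors fired at
#' the same trap on the same occasion. Simultaneity is declared, not inferred
#' from mere co-occurrence.
#'
#' @param simPairs two-column integer matrix of verified simultaneous pairs
#'   (detector-1 row, detector-2 row); one row per pair-generating event (or
#'   individual); duplicates collapse.
#' @param nObs1,nObs2 numbers of observed rows on each side.
#' @return an [IdentityInfo-class].
#' @export
findFullIdentities <- function(simPairs, nObs1, nObs2) {
  simPairs <- matrix(as.integer(simPairs), ncol = 2L)
  simPairs <- unique(simPairs)
  if (nrow(simPairs)) {
    if (anyDuplicated(simPairs[, 1L]))
      stop("identity conflict: a detector-1 row is claimed by two detector-2 rows")
    if (anyDuplicated(simPairs[, 2L]))
      stop("identity conflict: a detector-2 row is claimed by two detector-1 rows")
  }
  identityInfo(knownLinks = simPairs,
               free1 = setdiff(seq_len(nObs1), simPairs[, 1L]),
               free2 = setdiff(seq_len(nObs2), simPairs[, 2L]))
}

#' Load bilateral capture data from event tables
#'
#' Builds zero-augmented detection arrays from long-format capture events and
#' a trap table, and derives the known identity links from events flagged as
#' simultaneous (same individual identifier recorded by both detectors at the
#' same trap and occasion with the `simultaneous` flag set).
#'
#' Duplicate (individual, detector, trap, occasion) events collapse to a
#' single binary detection with a warning. Individual identifiers are shared
#' across detectors only for fully identified individuals; partial histories
#' carry distinct identifiers per side.
#'
#' @param captureEvents data frame with columns `individual_id`, `detector`
#'   (1 or 2), `trap_id`, `occasion`, `simultaneous` (0/1) and optionally
#'   `sex` (`"M"`/`"F"`/`""`).
#' @param trapTable data frame with columns `trap_id`, `x`, `y`.
#' @param K number of occasions.
#' @param M augmented size.
#' @param space optional [StateSpace-class] used to validate trap positions.
#' @return list with elements `data` ([BilateralData-class]), `identity`
#'   ([IdentityInfo-class]) and `traps` ([TrapArray-class]).
#' @export
loadCaptureData <- function(captureEvents, trapTable, K, M, space = NULL) {
  K <- as.integer(K); M <- as.integer(M)
  traps <- trapArray(cbind(trapTable$x, trapTable$y), space = space,
                     trapIds = trapTable$trap_id)
  J <- nTraps(traps)
  ev <- as.data.frame(captureEvents)
  needed <- c("individual_id", "detector", "trap_id", "occasion", "simultaneous")
  if (!all(needed %in% names(ev)))
    stop("captureEvents must have columns: ", paste(needed, collapse = ", "))
  if (nrow(ev)) {
    if (!all(ev$detector %in% c(1L, 2L)))
      stop("format error: detector must be 1 or 2")
    if (!all(ev$occasion >= 1L & ev$occasion <= K))
      stop("format error: occasion out of range 1..K")
    trapIdx <- match(ev$trap_id, traps@trapIds)
    if (anyNA(trapIdx)) stop("format error: unknown trap_id in capture events")
    ev$trapIdx <- trapIdx
    dup <- duplicated(ev[, c("individual_id", "detector", "trapIdx", "occasion")])
    if (any(dup)) {
      warning(sum(dup), " duplicate event(s) collapsed to binary detections")
      ev <- ev[!dup, , drop = FALSE]
    }
  }
  ids1 <- unique(ev$individual_id[ev$detector == 1L])
  ids2 <- unique(ev$individual_id[ev$detector == 2L])
  if (M < max(length(ids1), length(ids2)))
    stop("capacity error: M is smaller than the number of observed individuals")
  Y1 <- array(0, dim = c(M, J, K))
  Y2 <- array(0, dim = c(M, J, K))
  sex1 <- rep(NA_integer_, M); sex2 <- rep(NA_integer_, M)
  sexCode <- function(s) {
    if (is.null(s)) return(NA_integer_)
    s <- toupper(trimws(as.character(s)))
    if (!length(s) || is.na(s) || s == "") NA_integer_
    else if (s %in% c("M", "MALE", "1")) 1L
    else if (s %in% c("F", "FEMALE", "0")) 0L
    else NA_integer_
  }
  for (side in 1:2) {
    ids <- if (side == 1L) ids1 else ids2
    for (i in seq_along(ids)) {
      rows <- ev$detector == side & ev$individual_id == ids[[i]]
      idx <- cbind(i, ev$trapIdx[rows], ev$occasion[rows])
      if (side == 1L) Y1[idx] <- 1 else Y2[idx] <- 1
      if ("sex" %in% names(ev)) {
        sx <- sexCode(ev$sex[rows][1L])
        if (side == 1L) sex1[i] <- sx else sex2[i] <- sx
      }
    }
  }
  # simultaneous events shared across detectors under one identifier -> link
  sim <- ev[ev$simultaneous == 1L, , drop = FALSE]
  pairs <- matrix(integer(), ncol = 2L)
  if (nrow(sim)) {
    key1 <- sim[sim$detector == 1L, c("individual_id", "trapIdx", "occasion")]
    key2 <- sim[sim$detector == 2L, c("individual_id", "trapIdx", "occasion")]
    shared <- merge(key1, key2, by = c("individual_id", "trapIdx", "occasion"))
    if (nrow(shared)) {
      linkedIds <- unique(shared$individual_id)
      pairs <- cbind(match(linkedIds, ids1), match(linkedIds, ids2))
      pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
    }
  }
  identity <- findFullIdentities(pairs, length(ids1), length(ids2))
  # sex recorded on detector 2 for a linked pair attaches to the detector-1 row
  if (nrow(identity@knownLinks)) {
    kl <- identity@knownLinks
    take <- is.na(sex1[kl[, 1L]]) & !is.na(sex2[kl[, 2L]])
    sex1[kl[take, 1L]] <- sex2[kl[take, 2L]]
    sex2[kl[, 2L]] <- NA_integer_
  }
  list(data = bilateralData(Y1, Y2, sex1 = sex1, sex2 = sex2),
       identity = identity, traps = traps)
}

#' Read the CSV surfaces produced or consumed by the package
#'
#' @param dir directory holding `traps.csv`, `captures.csv` and (optionally)
#'   `identities.csv`.
#' @param K,M,space passed to [loadCaptureData()].
#' @return as [loadCaptureData()].
#' @export
readCaptureDir <- function(dir, K, M, space = NULL) {
  ev <- read.csv(file.path(dir, "captures.csv"))
  tr <- read.csv(file.path(dir, "traps.csv"))
  loadCaptureData(ev, tr, K = K, M = M, space = space)
}

#' Reorder detector-2 rows by an identity permutation
#'
#' Row i of the output is the detector-2 history whose true index is i, i.e.
#' `out[L[r], , ] = Y2[r, , ]`. Applying a permutation and then its inverse
#' restores the input, and sequential application composes as a group action.
#'
#' @param Y2 binary M x J x K array.
#' @param L integer permutation of 1..M; `L[r]` is the true index of row r.
#' @return the reordered array.
#' @export
reorderByPermutation <- function(Y2, L) {
  M <- dim(Y2)[1L]
  L <- as.integer(L)
  if (length(L) != M || !setequal(L, seq_len(M)))
    stop("L must be a bijection on 1..M")
  out <- Y2
  out[L, , ] <- Y2
  out
}

#' Inverse of an identity permutation
#' @param L integer permutation.
#' @return the inverse permutation.
#' @export
invertPermutation <- function(L) {
  inv <- integer(length(L))
  inv[L] <- seq_along(L)
  inv
}

# Internal: per-individual count matrices for a given assignment.
# assignment a: a[i] = detector-2 row occupying slot i (a = invertPermutation(L)).
captureCounts <- function(data, L) {
  M <- nAugmented(data); J <- nTraps(data); K <- nOccasions(data)
  a <- invertPermutation(L)
  C1 <- apply(data@Y1, c(1L, 2L), sum)
  C2 <- apply(data@Y2, c(1L, 2L), sum)[a, , drop = FALSE]
  ov <- matrix(0, M, J)
  for (j in seq_len(J)) {
    m1 <- matrix(data@Y1[, j, ], M, K)
    m2 <- matrix(data@Y2[, j, ], M, K)[a, , drop = FALSE]
    ov[, j] <- rowSums(m1 * m2)
  }
  nij <- C1 + C2 - ov
  list(nij = nij, yijDot = C1 + C2, yDotDot = rowSums(C1) + rowSums(C2),
       nDot = rowSums(nij), assignment = a)
}

#' Write a simulated or loaded data set to CSV surfaces
#'
#' @param data a [BilateralData-class].
#' @param identity an [IdentityInfo-class].
#' @param traps a [TrapArray-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCaptureDir <- function(data, identity, traps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  co <- trapCoords(traps)
  write.csv(data.frame(trap_id = traps@trapIds, x = co[, 1L], y = co[, 2L]),
            file.path(dir, "traps.csv"), row.names = FALSE)
  sexChar <- function(s) ifelse(is.na(s), "", ifelse(s == 1L, "M", "F"))
  rows <- list()
  emit <- function(Y, side, prefix, sex) {
    nr <- if (side == 1L) data@nObs1 else data@nObs2
    for (i in seq_len(nr)) {
      w <- which(Y[i, , ] == 1, arr.ind = TRUE)
      if (!length(w)) next
      w <- matrix(w, ncol = 2L)
      rows[[length(rows) + 1L]] <<- data.frame(
        individual_id = paste0(prefix, i), detector = side,
        trap_id = traps@trapIds[w[, 1L]], occasion = w[, 2L],
        simultaneous = 0L, sex = sexChar(sex[i]))
    }
  }
  emit(data@Y1, 1L, "d1_", data@sex1)
  emit(data@Y2, 2L, "d2_", data@sex2)
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(individual_id = character(), detector = integer(),
               trap_id = integer(), occasion = integer(),
               simultaneous = integer(), sex = character())
  # rewrite linked pairs under a shared identifier with simultaneity flags
  kl <- knownLinks(identity)
  if (nrow(kl)) {
    for (q in seq_len(nrow(kl))) {
      i <- kl[q, 1L]; r <- kl[q, 2L]
      id1 <- paste0("d1_", i); id2 <- paste0("d2_", r)
      ev$individual_id[ev$individual_id %in% c(id1, id2)] <- paste0("ind_", i)
      both <- (data@Y1[i, , ] * data@Y2[r, , ]) == 1
      w <- which(both, arr.ind = TRUE)
      if (length(w)) {
        w <- matrix(w, ncol = 2L)
        hit <- ev$individual_id == paste0("ind_", i) &
          paste(match(ev$trap_id, traps@trapIds), ev$occasion) %in%
            paste(w[, 1L], w[, 2L])
        ev$simultaneous[hit] <- 1L
      }
    }
  }
  write.csv(ev, file.path(dir, "captures.csv"), row.names = FALSE)
  if (nrow(kl))
    write.csv(data.frame(detector1_id = kl[, 1L], detector2_id = kl[, 2L]),
              file.path(dir, "identities.csv"), row.names = FALSE)
  invisible(dir)
}
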