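## Independent brute-force oracles and fixture builders. Everything here is
## deliberately written with explicit loops and its own arithmetic, separate
## from the package's vectorized implementations.

SP1 <- "Pelagia_noctiluca"

## exact IoU by counting unit grid cells; exact for integer-aligned boxes
rasterIoU <- function(a, b, size = 70) {
  cells <- function(bx) {
    m <- matrix(FALSE, size, size)
    if (bx[3] > bx[1] && bx[4] > bx[2]) {
      m[(bx[1] + 1):bx[3], (bx[2] + 1):bx[4]] <- TRUE
    }
    m
  }
  A <- cells(a)
  B <- cells(b)
  sum(A & B) / sum(A | B)
}

## second, loop-style analytic IoU used inside the other oracles
oracleIoU <- function(a, b) {
  ix <- min(a[3], b[3]) - max(a[1], b[1])
  iy <- min(a[4], b[4]) - max(a[2], b[2])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  areaA <- (a[3] - a[1]) * (a[4] - a[2])
  areaB <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (areaA + areaB - inter)
}

detBoxes <- function(d) {
  cbind(d$xmin, d$ymin, d$xmax, d$ymax)
}

## greedy NMS by repeated keep-max-and-delete, O(n^2)
nmsOracle <- function(dets, thr) {
  boxes <- detBoxes(dets)
  idx <- seq_len(nrow(dets))
  kept <- integer()
  while (length(idx)) {
    o <- order(-dets$confidence[idx], dets$xmin[idx], dets$ymin[idx])
    best <- idx[o[1]]
    kept <- c(kept, best)
    idx <- setdiff(idx, best)
    drop <- logical(length(idx))
    for (j in seq_along(idx)) {
      if (oracleIoU(boxes[best, ], boxes[idx[j], ]) > thr) drop[j] <- TRUE
    }
    idx <- idx[!drop]
  }
  sort(kept)
}

## independent per-frame per-class greedy matcher; returns tp/fp/fn totals
matchOracle <- function(preds, gtdf, thrIoU = 0.5) {
  matched <- rep(FALSE, nrow(gtdf))
  tp <- 0L
  fp <- 0L
  ord <- order(preds$frame, preds$class, -preds$confidence, preds$xmin)
  pb <- detBoxes(preds)
  gb <- detBoxes(gtdf)
  for (i in ord) {
    best <- -1
    bj <- 0L
    for (j in seq_len(nrow(gtdf))) {
      if (matched[j]) next
      if (gtdf$frame[j] != preds$frame[i]) next
      if (gtdf$class[j] != preds$class[i]) next
      v <- oracleIoU(pb[i, ], gb[j, ])
      if (v > best) {
        best <- v
        bj <- j
      }
    }
    if (bj > 0L && best >= thrIoU) {
      matched[bj] <- TRUE
      tp <- tp + 1L
    } else {
      fp <- fp + 1L
    }
  }
  c(tp = tp, fp = fp, fn = nrow(gtdf) - tp)
}

## exhaustive PR staircase: re-match the top-k ranking from scratch for
## every k, then integrate the monotone envelope with an explicit scan
apOracle <- function(preds, gtdf, classLabel, thrIoU = 0.5) {
  g <- gtdf[gtdf$class == classLabel, , drop = FALSE]
  G <- nrow(g)
  d <- preds[preds$class == classLabel, , drop = FALSE]
  if (!nrow(d)) return(0)
  d <- d[order(-d$confidence, d$frame, d$xmin), , drop = FALSE]
  n <- nrow(d)
  db <- detBoxes(d)
  gb <- detBoxes(g)
  recs <- numeric(n)
  precs <- numeric(n)
  for (k in seq_len(n)) {
    matched <- rep(FALSE, G)
    tp <- 0L
    for (i in seq_len(k)) {
      best <- -1
      bj <- 0L
      for (j in seq_len(G)) {
        if (matched[j] || g$frame[j] != d$frame[i]) next
        v <- oracleIoU(db[i, ], gb[j, ])
        if (v > best) {
          best <- v
          bj <- j
        }
      }
      if (bj > 0L && best >= thrIoU) {
        matched[bj] <- TRUE
        tp <- tp + 1L
      }
    }
    recs[k] <- tp / G
    precs[k] <- tp / k
  }
  ap <- 0
  prevR <- 0
  for (k in seq_len(n)) {
    if (recs[k] > prevR) {
      ap <- ap + (recs[k] - prevR) * max(precs[k:n])
      prevR <- recs[k]
    }
  }
  ap
}

## exhaustive Cthr1 sweep using the independent matcher
sweepOracle <- function(preds, gtdf, thrIoU = 0.5) {
  f1s <- numeric(101)
  for (t in 0:100) {
    keep <- preds$confidence * 100 >= t
    m <- matchOracle(preds[keep, , drop = FALSE], gtdf, thrIoU)
    p <- if (m["tp"] + m["fp"] > 0) m[["tp"]] / (m[["tp"]] + m[["fp"]]) else 0
    r <- if (m["tp"] + m["fn"] > 0) m[["tp"]] / (m[["tp"]] + m[["fn"]]) else 0
    f1s[t + 1] <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  list(f1 = f1s, best = which.max(f1s) - 1L)
}

## pointwise similarity comparison loop
similarityOracle <- function(predFrames, predCounts, truthFrames, truthCounts) {
  ok <- 0L
  for (i in seq_along(predFrames)) {
    j <- which(truthFrames == predFrames[i])
    if (all(predCounts[i, colnames(truthCounts)] == truthCounts[j, ])) {
      ok <- ok + 1L
    }
  }
  100 * ok / length(predFrames)
}

## window-by-window mode reduction with explicit enumeration (same
## tie-break contract: previous value, then lower count)
windowOracle <- function(counts, wSize, stride) {
  n <- nrow(counts)
  starts <- integer()
  s <- 1L
  while (s + wSize - 1L <= n) {
    starts <- c(starts, s)
    s <- s + stride
  }
  out <- matrix(0L, length(starts), ncol(counts),
                dimnames = list(NULL, colnames(counts)))
  for (j in seq_len(ncol(counts))) {
    prev <- NA_integer_
    for (w in seq_along(starts)) {
      v <- counts[starts[w]:(starts[w] + wSize - 1L), j]
      tb <- table(v)
      top <- as.integer(names(tb)[tb == max(tb)])
      val <- if (length(top) == 1L) top
             else if (!is.na(prev) && prev %in% top) prev
             else min(top)
      out[w, j] <- val
      prev <- val
    }
  }
  list(ends = starts + wSize - 1L, counts = out)
}

## ---- fixture builders ----

randomDetFrame <- function(n, frame = 0L, classes = SP1, maxCoord = 60L) {
  if (n == 0L) {
    out <- emptyDetectionTable()
    return(out)
  }
  xmin <- sample.int(maxCoord - 10L, n, replace = TRUE) - 1L
  ymin <- sample.int(maxCoord - 10L, n, replace = TRUE) - 1L
  data.frame(
    frame = frame,
    class = sample(classes, n, replace = TRUE),
    confidence = sample(seq(0.01, 0.99, by = 0.0001), n),
    xmin = xmin, ymin = ymin,
    xmax = xmin + sample(3:10, n, replace = TRUE),
    ymax = ymin + sample(3:10, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

randomAnnotation <- function(nObjects, frame = 0L, classes = SP1,
                             width = 64, height = 64) {
  ob <- randomDetFrame(nObjects, frame, classes)
  FrameAnnotation(frame, width, height,
                  ob[, c("class", "xmin", "ymin", "xmax", "ymax")])
}

gtTableOf <- function(anns) {
  rows <- lapply(anns, function(a) {
    ob <- annotationObjects(a)
    if (!nrow(ob)) return(NULL)
    cbind(data.frame(frame = frameIds(a)), ob)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(cbind(data.frame(frame = integer()), emptyObjectTable()))
  }
  do.call(rbind, rows)
}

## scene whose species count stays constant and positive for its whole
## duration: one long-dwelling individual, effectively no turnover
constantScene <- function(duration = 120, fps = 1.6, maxSeed = 50) {
  params <- sceneParams(
    duration = duration, fps = fps, species = SP1,
    arrivalRate = 1e-4, dwellMean = 1e4
  )
  for (seed in seq_len(maxSeed)) {
    sc <- generateScene(params, seed = seed)
    cnt <- countMatrix(sc$timeline)
    if (cnt[1] > 0 && all(cnt == cnt[1])) {
      attr(sc, "seed") <- seed
      return(sc)
    }
  }
  stop("no constant-count seed found")
}

## information points with a given count vector per frame
ipointsOf <- function(counts, fps = 1.6, class = SP1) {
  m <- matrix(as.integer(counts), ncol = 1, dimnames = list(NULL, class))
  InformationPoints(seq_along(counts) - 1L, m, (seq_along(counts) - 1L) / fps)
}

timelineOf <- function(counts, class = SP1) {
  m <- matrix(as.integer(counts), ncol = 1, dimnames = list(NULL, class))
  CountTimeline(seq_along(counts) - 1L, m)
}
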