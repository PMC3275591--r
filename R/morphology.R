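## 3D binary morphology on logical arrays, via vectorised shifts.
## The structuring element is the 6-connected unit ball (face neighbours);
## radius r means r successive applications, i.e. an L1 ball of radius r.

unitShifts6 <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

dilate3d <- function(a, radius = 1L) {
    for (i in seq_len(radius)) {
        out <- a
        for (s in unitShifts6)
            out <- out | shift3d(a, s[1], s[2], s[3], fill = FALSE)
        a <- out
    }
    a
}

erode3d <- function(a, radius = 1L) {
    for (i in seq_len(radius)) {
        out <- a
        for (s in unitShifts6)
            out <- out & shift3d(a, s[1], s[2], s[3], fill = FALSE)
        a <- out
    }
    a
}

closing3d <- function(a, radius = 1L) {
    if (radius < 1L) return(a)
    erode3d(dilate3d(a, radius), radius)
}

opening3d <- function(a, radius = 1L) {
    if (radius < 1L) return(a)
    dilate3d(erode3d(a, radius), radius)
}

## 26-connectivity connected-component labelling by iterative minimum-label
## propagation.  Adequate for the desk-scale grids this package works on.
labelComponents26 <- function(a) {
    d <- dim(a)
    lab <- array(Inf, d)
    lab[a] <- which(a)
    shifts <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0 & shifts$dz == 0), ]
    repeat {
        nxt <- lab
        for (i in seq_len(nrow(shifts))) {
            sh <- shift3d(lab, shifts$dx[i], shifts$dy[i], shifts$dz[i],
                          fill = Inf)
            nxt <- pmin(nxt, sh)
        }
        nxt[!a] <- Inf
        if (identical(nxt, lab)) break
        lab <- nxt
    }
    out <- array(0L, d)
    if (any(a)) out[a] <- as.integer(match(lab[a], sort(unique(lab[a]))))
    out
}

largestComponent26 <- function(a) {
    lab <- labelComponents26(a)
    if (!any(a)) return(a)
    tb <- tabulate(lab[lab > 0])
    lab == which.max(tb)
}
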