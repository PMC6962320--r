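# Shared fixtures: tiny volumes and hand-built patches, all generated in code.

const_volume <- function(value = -1000, dims = c(64L, 64L, 16L),
                         spacing = c(1, 1, 1), mask = FALSE) {
  v <- array(value, dim = dims)
  ct_volume(v, spacing = spacing,
            lung_mask = if (mask) array(1L, dim = dims) else NULL)
}

# voxel value equals its z index (1-based)
zramp_volume <- function(dims = c(64L, 64L, 16L)) {
  v <- array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dim = dims)
  ct_volume(v)
}

# a bare roi_sample around a given matrix/array (bypasses extraction)
make_sample <- function(data, mode = "axial2d", label = "NP",
                        normalized = FALSE, context = NULL) {
  structure(list(mode = mode, data = data, context = context, label = label,
                 coord = c(1L, 1L, 1L), scan_id = "fix",
                 normalized = normalized),
            class = "roi_sample")
}

rand_patch <- function(size = 48L, mean = -850, sd = 100) {
  matrix(rnorm(size * size, mean, sd), size, size)
}

# annotation table with given per-class counts (coordinates are dummies)
count_points <- function(counts, n_subjects = 20L) {
  data.frame(scan_id = "scan",
             subject_id = rep(paste0("sub", seq_len(n_subjects)),
                              length.out = sum(counts)),
             i = 50L, j = 50L, k = 5L,
             label = rep(names(counts), counts),
             kernel = "B50", stringsAsFactors = FALSE)
}

# the clinical annotation-count skew used for split arithmetic
clinical_counts <- function() {
  c(NP = 23696L, GG = 137L, RETIC = 5409L, NOD = 117L, LINSC = 195L,
    SUBPL = 413L, PS = 3845L, CL = 3613L)
}
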