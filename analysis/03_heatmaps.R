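#!/usr/bin/env Rscript
# Marker-distribution maps on a synthetic central nucleus: projects the
# 3D marker coordinates onto the coronal plane, smooths them into a
# density grid, and overlays the averaged section contour. Writes
# results/cn_heatmap.png and the raw grid as results/cn_heatmap.tsv.

suppressPackageStartupMessages(library(stereofract))

v_mm3 <- 136.2
base_ax <- c(9000, 5500, 13740)
ax <- base_ax * (v_mm3 * 1e9 / (4 / 3 * pi * prod(base_ax)))^(1 / 3)
cn <- make_region("CN-small", list(type = "ellipsoid", semi_axes_um = ax))

# an inhomogeneous touch: a dorsomedial concentration on top of the
# uniform field, mimicking the gradient real nuclei display
pts <- simulate_neuron_field(
  cn, 3561, c(nuclear = 0.71, cytoplasmic = 0.009, both = 0.14, none = 0.141),
  seed = 99
)
set.seed(100)
hot <- pts[sample.int(nrow(pts), round(nrow(pts) * 0.3)), ]
hot$x_um <- hot$x_um * 0.4 + 0.35 * ax[1]
hot$y_um <- hot$y_um * 0.4 + 0.35 * ax[2]
pts <- rbind(pts, hot[point_in_region(cn, cbind(hot$x_um, hot$y_um, hot$z_um)), ])

# averaged contour over every 30th section, as traced on the slides
st <- section_stack(cn, points = pts, cut_thickness_um = 50)
polys <- Filter(Negate(is.null),
                lapply(seq(0, st$n_sections - 1, by = 30),
                       function(s) section_polygon(st, s)))
avg <- average_contour(polys, n_vertices = 200)

hm <- marker_heatmap(pts, pixel_size_um = 100, bandwidth_um = 250,
                     contours = list(avg))

dir.create("results", showWarnings = FALSE)
grDevices::png("results/cn_heatmap.png", width = 900, height = 700, res = 110)
plot(hm, main = "synthetic CN, amyloid-beta marker density")
grDevices::dev.off()
write_heatmap_tsv(hm, "results/cn_heatmap.tsv")
message(sprintf("heatmap: %d points, %d x %d pixels, peak at (%.0f, %.0f) um",
                nrow(pts), length(hm$x_centers), length(hm$y_centers),
                hm$x_centers[which(hm$intensity == 1, arr.ind = TRUE)[1, 1]],
                hm$y_centers[which(hm$intensity == 1, arr.ind = TRUE)[1, 2]]))
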