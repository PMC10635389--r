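# Data dictionary

All files are plain UTF-8. CSVs are comma-delimited with a header row.
Coordinates are micrometres in the image convention: origin top-left,
x rightward, y downward. Angles are axial degrees in [0, 180) measured from
the +x axis.

## cells.csv (segmentation-level cell table)

| column | type | meaning |
|---|---|---|
| cell_id | int | unique cell id |
| mouse | str | section/animal id, `<GROUP>_m<NN>` |
| group | str | experimental group (e.g. YNG, OLD) |
| region | str | region label (hippocampus, fimbria) |
| x, y | num | centroid (um) |
| area_um2 | num | cell area (um^2); equals the shoelace area of `polygon` |
| polygon | str | vertex list `"x1 y1;x2 y2;..."` (um) |
| intden_<CH> | num | integrated density for channel CH (a.u.) |
| bg_<CH> | num | mean local background for channel CH (a.u./um^2), shared within a section |

Channels: IBA1, GAL3, APOE.

## tracts.csv (fiber-tract segments)

tract_id (int), region (str), x1, y1, x2, y2 (num, um), angle (num, axial
degrees).

## scene.json (section geometry)

`regions` (named polygons, n x 2 vertex arrays), `midline` (fimbria midline
polyline), `ventricle_edge` (polyline), `um_per_unit` (scale).

## truth.csv (simulation ground truth; consumed only by tests)

cell_id (int), subtype ("spindle"|"ramified"), gal3_pos (bool), apoe_pos
(bool).

## morphometrics.csv (one row per cell)

cell_id, mouse, group, region, feret_length (um), feret_angle (deg),
area (um^2), perimeter (um), circularity (4*pi*A/P^2), nearest_tract (id),
tract_distance (um), angle_offset (deg in [0, 90]), and per channel:
tccf_<CH> (a.u.), tccf_neg_<CH> (bool, negative-TCCF flag), norm_<CH>
(control-normalized, min-max scaled to [0, 1]).

## Count matrix (MTX directory)

- `counts.mtx`: MatrixMarket coordinate format, 1-based, cells x genes.
- `cells.csv`: cell_id, x, y, fov, region (row order matches the matrix).
- `genes.csv`: gene (column order matches the matrix).

Long-CSV alternative: cell_id, gene, count (+ optional x, y, fov, region);
duplicate (cell, gene) rows are summed with a warning.

## qpcr.csv

sample, group, gene, Ct (+ optional sex, tissue). One housekeeper row
(Hprt) per sample.

## aoi_counts.csv

Genes x AOIs, first column = row names; negative probes as rows named
`NegProbe*`.

## Pipeline outputs

clusters.csv (cell_id, cluster), enrichment.csv (cell_id, enriched),
de.csv (gene, log2fc, p, padj, direction), stats.json (thresholds, KS
results, per-group summaries), manifest.json (config, seed, stage order,
md5 checksum per output).
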