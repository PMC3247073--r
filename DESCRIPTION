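Package: endicom
Title: Sentinel-Voxel Marking of Intraoperative Tumor Landmarks in CT DICOM Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for carrying intraoperatively acquired, histology-classified
    3D landmark points from an image-guided surgery workflow into radiotherapy
    planning. Landmarks recorded in the navigation frame are mapped into the
    image frame by paired-point rigid (fiducial) registration, tumor-positive
    points are written into a copy of the patient's CT DICOM series as
    sentinel-intensity voxels (3500 HU, above the conventional CT range), and
    downstream software recovers them by simple threshold segmentation. The
    package includes a self-contained DICOM CT series reader/writer
    (uncompressed little-endian), margin-augmented threshold segmentation with
    a millimetre-metric distance-transform dilation, sagittal mask mirroring,
    landmark-based rigid volume fusion, and a synthetic head-phantom generator
    so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
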