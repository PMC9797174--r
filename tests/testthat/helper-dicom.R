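# Builds tiny DICOM RT files with pydicom at test time (binary stays in
# tempdir; the repository carries no binary fixtures).

make_test_dicom <- function(what = c("rtdose", "rtstruct"), path) {
  what <- match.arg(what)
  py <- Sys.which("python")
  script <- tempfile(fileext = ".py")
  if (what == "rtdose") {
    code <- '
import sys
import numpy as np
import pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid

ds = Dataset()
ds.SOPClassUID = "1.2.840.10008.5.1.4.1.1.481.2"
ds.SOPInstanceUID = generate_uid()
ds.Modality = "RTDOSE"
ds.FrameOfReferenceUID = "FOR-T"
ds.ImagePositionPatient = [1.0, 2.0, 3.0]
ds.ImageOrientationPatient = [1, 0, 0, 0, 1, 0]
ds.PixelSpacing = [2.0, 1.5]          # (row=y, col=x)
ds.GridFrameOffsetVector = [0.0, 2.5, 5.0]
ds.Rows = 4
ds.Columns = 5
ds.NumberOfFrames = 3
ds.DoseGridScaling = 0.001
ds.DoseUnits = "GY"
ds.BitsAllocated = 16
ds.BitsStored = 16
ds.HighBit = 15
ds.PixelRepresentation = 0
ds.SamplesPerPixel = 1
ds.PhotometricInterpretation = "MONOCHROME2"
zz, yy, xx = np.meshgrid(np.arange(3), np.arange(4), np.arange(5), indexing="ij")
arr = (2000 + xx + 10 * yy + 100 * zz).astype(np.uint16)
ds.PixelData = arr.tobytes()
meta = FileMetaDataset()
meta.TransferSyntaxUID = ExplicitVRLittleEndian
meta.MediaStorageSOPClassUID = ds.SOPClassUID
meta.MediaStorageSOPInstanceUID = ds.SOPInstanceUID
ds.file_meta = meta
ds.save_as(sys.argv[1], enforce_file_format=True)
'
  } else {
    code <- '
import sys
import pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid

ds = Dataset()
ds.SOPClassUID = "1.2.840.10008.5.1.4.1.1.481.3"
ds.SOPInstanceUID = generate_uid()
ds.Modality = "RTSTRUCT"
roi = Dataset()
roi.ROINumber = 1
roi.ROIName = "PTV1"
roi.ReferencedFrameOfReferenceUID = "FOR-T"
ds.StructureSetROISequence = [roi]
c = Dataset()
c.ContourGeometricType = "CLOSED_PLANAR"
c.NumberOfContourPoints = 4
c.ContourData = [0.0, 0.0, 5.0, 20.0, 0.0, 5.0, 20.0, 20.0, 5.0, 0.0, 20.0, 5.0]
rc = Dataset()
rc.ReferencedROINumber = 1
rc.ContourSequence = [c]
ds.ROIContourSequence = [rc]
meta = FileMetaDataset()
meta.TransferSyntaxUID = ExplicitVRLittleEndian
meta.MediaStorageSOPClassUID = ds.SOPClassUID
meta.MediaStorageSOPInstanceUID = ds.SOPInstanceUID
ds.file_meta = meta
ds.save_as(sys.argv[1], enforce_file_format=True)
'
  }
  writeLines(code, script)
  out <- suppressWarnings(system2(py, c(shQuote(script), shQuote(path)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("test DICOM generation failed: ", paste(out, collapse = "\n"))
  }
  path
}
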