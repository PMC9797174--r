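"""Convert DICOM RT Dose / RT Structure Set objects to rtspc JSON fixtures.

Usage: python dicom_to_fixture.py {rtdose|rtstruct} <in.dcm> <out.json>

RT Dose: dose is scaled to Gy via DoseGridScaling; geometry comes from
ImagePositionPatient (mm, first voxel center), PixelSpacing (row=y, col=x)
and GridFrameOffsetVector (z). Only axis-aligned orientation and uniform
slice spacing are accepted. Values are emitted flat with x varying fastest.

RT Struct: CLOSED_PLANAR contours only; each contour must lie on a constant
axial plane.
"""
import json
import sys

import pydicom


def fail(msg):
    sys.stderr.write(msg + "\n")
    sys.exit(1)


def convert_rtdose(ds):
    if getattr(ds, "Modality", None) != "RTDOSE":
        fail("not an RT Dose object (Modality != RTDOSE)")
    for tag in ("ImagePositionPatient", "PixelSpacing", "GridFrameOffsetVector",
                "Rows", "Columns", "DoseGridScaling"):
        if not hasattr(ds, tag):
            fail(f"missing geometry tag {tag}")
    iop = [float(v) for v in getattr(ds, "ImageOrientationPatient",
                                     [1, 0, 0, 0, 1, 0])]
    if iop != [1, 0, 0, 0, 1, 0]:
        fail("oblique ImageOrientationPatient not supported")
    offsets = [float(v) for v in ds.GridFrameOffsetVector]
    if len(offsets) < 1:
        fail("empty GridFrameOffsetVector")
    if len(offsets) > 1:
        steps = [offsets[i + 1] - offsets[i] for i in range(len(offsets) - 1)]
        if max(steps) - min(steps) > 1e-6:
            fail("non-uniform slice spacing in GridFrameOffsetVector")
        dz = steps[0]
        if dz <= 0:
            fail("non-positive spacing in GridFrameOffsetVector")
    else:
        dz = float(getattr(ds, "SliceThickness", 0) or 0)
        if dz <= 0:
            fail("cannot determine slice spacing (single frame, no SliceThickness)")
    dy, dx = (float(v) for v in ds.PixelSpacing)  # PixelSpacing = (row, col)
    arr = ds.pixel_array  # (frames, rows, cols) or (rows, cols)
    if arr.ndim == 2:
        arr = arr[None, :, :]
    scale = float(ds.DoseGridScaling)
    dose = (arr.astype("float64") * scale)
    nz, ny, nx = dose.shape
    pos = [float(v) for v in ds.ImagePositionPatient]
    origin = [pos[0], pos[1], pos[2] + offsets[0]]
    return {
        "origin": origin,
        "spacing": [dx, dy, dz],
        "shape": [nx, ny, nz],
        "frame_id": str(getattr(ds, "FrameOfReferenceUID", "FOR-1")),
        # C-order flatten of (z, y, x) iterates x fastest, matching the
        # fixture convention.
        "values": dose.flatten().tolist(),
    }


def convert_rtstruct(ds):
    if getattr(ds, "Modality", None) != "RTSTRUCT":
        fail("not an RT Structure Set object (Modality != RTSTRUCT)")
    names = {}
    frame_id = "FOR-1"
    for roi in getattr(ds, "StructureSetROISequence", []):
        names[int(roi.ROINumber)] = str(roi.ROIName)
        frame_id = str(getattr(roi, "ReferencedFrameOfReferenceUID", frame_id))
    structures = []
    for rc in getattr(ds, "ROIContourSequence", []):
        name = names.get(int(rc.ReferencedROINumber))
        if name is None:
            continue
        contours = []
        for c in getattr(rc, "ContourSequence", []):
            if str(getattr(c, "ContourGeometricType", "CLOSED_PLANAR")) != "CLOSED_PLANAR":
                continue
            data = [float(v) for v in c.ContourData]
            pts = [data[i:i + 3] for i in range(0, len(data), 3)]
            zs = {round(p[2], 6) for p in pts}
            if len(zs) != 1:
                fail(f"non-planar contour in ROI '{name}'")
            contours.append({"z": pts[0][2],
                             "vertices": [[p[0], p[1]] for p in pts]})
        if contours:
            structures.append({"name": name, "contours": contours})
    if not structures:
        fail("no structures")
    return {"frame_id": frame_id, "structures": structures}


def main():
    if len(sys.argv) != 4 or sys.argv[1] not in ("rtdose", "rtstruct"):
        fail("usage: dicom_to_fixture.py {rtdose|rtstruct} <in.dcm> <out.json>")
    mode, inp, outp = sys.argv[1:4]
    try:
        ds = pydicom.dcmread(inp, force=True)
    except Exception as e:  # noqa: BLE001
        fail(f"unreadable DICOM file '{inp}': {e}")
    obj = convert_rtdose(ds) if mode == "rtdose" else convert_rtstruct(ds)
    with open(outp, "w", encoding="utf-8") as fh:
        json.dump(obj, fh)


if __name__ == "__main__":
    main()
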