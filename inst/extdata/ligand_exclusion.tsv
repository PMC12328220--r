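resid	note
HOH	water
WAT	water
DOD	heavy water
SO4	sulfate buffer
PO4	phosphate buffer
GOL	glycerol cryoprotectant
EDO	ethylene glycol cryoprotectant
PEG	polyethylene glycol
PG4	polyethylene glycol
MPD	hexanediol cryoprotectant
ACT	acetate buffer
DMS	dimethyl sulfoxide
TRS	tris buffer
MES	MES buffer
EPE	HEPES buffer
CIT	citrate buffer
TLA	tartrate buffer
FMT	formate
EOH	ethanol
IPA	isopropanol
BME	beta-mercaptoethanol
NO3	nitrate
CL	chloride ion
BR	bromide ion
IOD	iodide ion
NA	sodium ion
K	potassium ion
CS	cesium ion
NH4	ammonium ion
AZI	azide
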