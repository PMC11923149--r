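ligand	description
GOL	glycerol
EDO	ethylene glycol
SO4	sulfate ion
PO4	phosphate ion
PEG	di(hydroxyethyl)ether
PG4	tetraethylene glycol
PGE	triethylene glycol
MPD	2-methyl-2,4-pentanediol
DMS	dimethyl sulfoxide
ACT	acetate ion
TRS	tris buffer
EPE	hepes buffer
MES	mes buffer
FMT	formic acid
NO3	nitrate ion
CIT	citrate
BME	beta-mercaptoethanol
IMD	imidazole
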