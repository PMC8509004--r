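structure_acronym	region
MFC	ACC
AMY	Amy
CBC	Cer
DFC	DLPC
HIP	Hipp
ITC	ITC
MD	MTh
OFC	OFC
STC	PSTC
IPC	PPC
A1C	PAC
M1C	PMC
V1C	PVC
S1C	PSSC
STR	Str
VFC	VLPC
ACC	ACC
Amy	Amy
Cer	Cer
DLPC	DLPC
Hipp	Hipp
MTh	MTh
PSTC	PSTC
PPC	PPC
PAC	PAC
PMC	PMC
PVC	PVC
PSSC	PSSC
Str	Str
VLPC	VLPC
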