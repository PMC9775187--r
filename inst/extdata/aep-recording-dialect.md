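# AEP recording XML dialect

One recording per file; root element `<AEPRecording>`. The tag names follow
the fields of clinical evoked-potential exports (dual acquisition buffers,
sampling metadata, optional clinician wave marks); everything else about the
proprietary export header is deliberately out of scope.

| Element | Content |
|---|---|
| `Subtype` | `ABR` or `AMLR` |
| `PatientID` | opaque identifier (may be empty) |
| `Ear` | `left`, `right` or `unknown` |
| `Intensity` | stimulus intensity in dB nHL (may be empty) |
| `SampleRate` | sampling rate in Hz (ABR 30000, AMLR 3000) |
| `PrestimulusSamples` | samples recorded before stimulus onset (metadata only; the time axis starts at 0 at the first stored sample) |
| `RawToMicrovolt` | multiplicative factor raw units -> microvolts |
| `IPSI_A_RAW` | buffer A samples, whitespace-separated decimal text |
| `IPSI_B_RAW` | buffer B samples, same length as buffer A |
| `Jewetts` | optional; one `<Jewett Wave="..." Sample="..."/>` child per annotated wave |

`Jewett/@Wave` is one of `I II III IV V` (ABR) or `Na Pa Nb Pb` (AMLR);
`Jewett/@Sample` is the **0-based** sample index of the wave's peak/trough.
R-side objects use 1-based indices; the reader and writer convert.

Example (truncated buffers):

```xml
<AEPRecording>
  <Subtype>ABR</Subtype>
  <PatientID>rec_0001</PatientID>
  <Ear>left</Ear>
  <Intensity>80</Intensity>
  <SampleRate>30000</SampleRate>
  <PrestimulusSamples>0</PrestimulusSamples>
  <RawToMicrovolt>0.01</RawToMicrovolt>
  <IPSI_A_RAW>-1.27 0.53 2.10 ...</IPSI_A_RAW>
  <IPSI_B_RAW>0.88 -0.41 1.95 ...</IPSI_B_RAW>
  <Jewetts>
    <Jewett Wave="I" Sample="45"/>
    <Jewett Wave="III" Sample="105"/>
    <Jewett Wave="V" Sample="165"/>
  </Jewetts>
</AEPRecording>
```
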