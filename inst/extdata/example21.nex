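#NEXUS
[ five-split system on taxa 1..5: 12|345, 23|145, 34|125, 45|123, 15|234 ]
BEGIN TAXA;
  DIMENSIONS NTAX=5;
  TAXLABELS
    1 2 3 4 5
  ;
END;
BEGIN SPLITS;
  DIMENSIONS NTAX=5 NSPLITS=5;
  FORMAT labels=no weights=yes confidences=no;
  CYCLE 1 2 3 4 5;
  MATRIX
    [1, size=2] 1.0 1 2,
    [2, size=2] 1.0 2 3,
    [3, size=2] 1.0 3 4,
    [4, size=2] 1.0 4 5,
    [5, size=2] 1.0 1 5,
  ;
END;
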