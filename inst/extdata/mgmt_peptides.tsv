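name	start	end	sequence
MGMT-01	1	20	MDKDCEMKRTTLDSPLGKLE
MGMT-02	11	30	TLDSPLGKLELSGCEQGLHE
MGMT-03	21	40	LSGCEQGLHEIKLLGKGTSA
MGMT-04	31	50	IKLLGKGTSAADAVEVPAPA
MGMT-05	41	59	ADAVEVPAPAAVLGGPELM
MGMT-06	51	68	AVLGGPELMQCTAWLNAYF
MGMT-07	60	79	QCTAWLNAYFHQPEAIEEFP
MGMT-08	70	89	HQPEAIEEFPVPALHHPVFQ
MGMT-09	80	99	VPALHHPVFQQESFTRQVLW
MGMT-10	90	109	QESFTRQVLWKLLKVVKFGE
MGMT-11	100	119	KLLKVVKFGEVISYQQLAAL
MGMT-12	110	129	VISYQQLAALAGNPKAARAV
MGMT-13	120	139	AGNPKAARAVGGAMRGNPVP
MGMT-14	130	149	GGAMRGNPVPILIPCHRVVC
MGMT-15	140	159	ILIPCHRVVCSSGAVGNYSG
MGMT-16	150	169	SSGAVGNYSGGLAVKEWLLA
MGMT-17	160	179	GLAVKEWLLAHEGHRLGKPG
MGMT-18	170	189	HEGHRLGKPGLGGSSGLAGA
MGMT-19	180	199	LGGSSGLAGAWLKGAGATSG
MGMT-20	190	206	WLKGAGATSGSPPAGRN
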