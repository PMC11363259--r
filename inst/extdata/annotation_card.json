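[
  {
    "name": "Mobilize Colon/Removal of Adhesions",
    "laterality": "none",
    "optional": true,
    "start_action": "First grasp of colon or adhesion tissue",
    "stop_action": "Colon mobile / adhesions released",
    "card_index": 1
  },
  {
    "name": "Dissection of Fallopian Tube",
    "laterality": "paired",
    "optional": true,
    "start_action": "First grasp of the fallopian tube",
    "stop_action": "Tube fully detached",
    "card_index": 2
  },
  {
    "name": "Dissection of IP Ligament",
    "laterality": "paired",
    "optional": true,
    "start_action": "First grasp of the infundibulopelvic ligament",
    "stop_action": "Ligament fully divided",
    "card_index": 3
  },
  {
    "name": "Dissection of Utero-Ovarian Ligament",
    "laterality": "paired",
    "optional": true,
    "start_action": "First grasp of the utero-ovarian ligament",
    "stop_action": "Ligament fully divided",
    "card_index": 4
  },
  {
    "name": "Division of the Round Ligament",
    "laterality": "paired",
    "optional": false,
    "start_action": "Instrument contacts the round ligament",
    "stop_action": "Ligament fully divided",
    "card_index": 5
  },
  {
    "name": "Division of the Broad Ligament",
    "laterality": "paired",
    "optional": false,
    "start_action": "Instrument contacts the broad ligament",
    "stop_action": "Broad ligament opened to planned extent",
    "card_index": 6
  },
  {
    "name": "Bladder Flap Creation",
    "laterality": "none",
    "optional": false,
    "start_action": "First incision of the vesicouterine peritoneum",
    "stop_action": "Bladder reflected off the cervix",
    "card_index": 7
  },
  {
    "name": "Division of Uterine Vessels",
    "laterality": "paired",
    "optional": false,
    "start_action": "Instrument contacts the uterine vessels",
    "stop_action": "Vessels sealed and divided",
    "card_index": 8
  },
  {
    "name": "Colpotomy",
    "laterality": "none",
    "optional": false,
    "start_action": "First incision of the vaginal wall",
    "stop_action": "Vagina opened circumferentially",
    "card_index": 9
  },
  {
    "name": "Removal of the Uterus",
    "laterality": "none",
    "optional": false,
    "start_action": "First traction on the detached uterus",
    "stop_action": "Uterus out of the operative field",
    "card_index": 10
  },
  {
    "name": "Vaginal Cuff Closure",
    "laterality": "none",
    "optional": false,
    "start_action": "Needle clamped in the needle holder",
    "stop_action": "Barbed thread cut after complete closure",
    "card_index": 11
  }
]
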