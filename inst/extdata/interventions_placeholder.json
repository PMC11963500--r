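[
  {
    "id": "safe_abortion_services",
    "period": "periconceptual",
    "targets": [
      {"cause": "abortion", "efficacy": 0.85, "affected_fraction": 1.0}
    ]
  },
  {
    "id": "tetanus_toxoid",
    "period": "pregnancy",
    "targets": [
      {"cause": "sepsis", "efficacy": 0.60, "affected_fraction": 1.0}
    ]
  },
  {
    "id": "micronutrient_supplementation",
    "period": "pregnancy",
    "targets": [
      {"cause": "antepartum_hemorrhage", "efficacy": 0.50, "affected_fraction": 1.0},
      {"cause": "postpartum_hemorrhage", "efficacy": 0.50, "affected_fraction": 1.0}
    ]
  },
  {
    "id": "hypertensive_case_management",
    "period": "pregnancy",
    "targets": [
      {"cause": "hypertensive_disorders", "efficacy": 0.70, "affected_fraction": 1.0}
    ]
  },
  {
    "id": "clean_birth_environment",
    "period": "childbirth",
    "targets": [
      {"cause": "sepsis", "efficacy": 0.55, "affected_fraction": 1.0}
    ]
  },
  {
    "id": "mgso4_eclampsia",
    "period": "childbirth",
    "targets": [
      {"cause": "hypertensive_disorders", "efficacy": 0.75, "affected_fraction": 1.0}
    ]
  },
  {
    "id": "antibiotics_prom",
    "period": "childbirth",
    "targets": [
      {"cause": "sepsis", "efficacy": 0.60, "affected_fraction": 1.0}
    ]
  },
  {
    "id": "antibiotics_maternal_sepsis",
    "period": "childbirth",
    "targets": [
      {"cause": "sepsis", "efficacy": 0.80, "affected_fraction": 1.0}
    ]
  },
  {
    "id": "assisted_vaginal_delivery",
    "period": "childbirth",
    "targets": [
      {"cause": "other_direct", "efficacy": 0.65, "affected_fraction": 1.0},
      {"cause": "intrapartum_hemorrhage", "efficacy": 0.60, "affected_fraction": 1.0}
    ]
  },
  {
    "id": "uterotonics_pph",
    "period": "childbirth",
    "targets": [
      {"cause": "postpartum_hemorrhage", "efficacy": 0.90, "affected_fraction": 1.0}
    ]
  },
  {
    "id": "manual_removal_placenta",
    "period": "childbirth",
    "targets": [
      {"cause": "postpartum_hemorrhage", "efficacy": 0.55, "affected_fraction": 1.0}
    ]
  },
  {
    "id": "removal_retained_products",
    "period": "childbirth",
    "targets": [
      {"cause": "postpartum_hemorrhage", "efficacy": 0.50, "affected_fraction": 1.0},
      {"cause": "abortion", "efficacy": 0.55, "affected_fraction": 1.0}
    ]
  },
  {
    "id": "cesarean_delivery",
    "period": "childbirth",
    "targets": [
      {"cause": "other_direct", "efficacy": 0.70, "affected_fraction": 1.0},
      {"cause": "antepartum_hemorrhage", "efficacy": 0.65, "affected_fraction": 1.0}
    ]
  },
  {
    "id": "blood_transfusion",
    "period": "childbirth",
    "targets": [
      {"cause": "antepartum_hemorrhage", "efficacy": 0.70, "affected_fraction": 1.0},
      {"cause": "intrapartum_hemorrhage", "efficacy": 0.70, "affected_fraction": 1.0},
      {"cause": "postpartum_hemorrhage", "efficacy": 0.70, "affected_fraction": 1.0}
    ]
  }
]
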