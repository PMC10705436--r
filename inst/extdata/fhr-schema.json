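{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "https://raw.githubusercontent.com/FAIR-bioHeaders/FHR-Specification/main/fhr.json",
  "title": "FHR",
  "description": "Local mirror of the FAIR Header Reference genome record model: nine required provenance fields plus eleven optional fields. Shipped with the package so validation never requires network access.",
  "type": "object",
  "required": [
    "schema",
    "schemaVersion",
    "genome",
    "taxon",
    "version",
    "assemblyAuthor",
    "metadataAuthor",
    "dateCreated",
    "checksum"
  ],
  "properties": {
    "schema": {
      "type": "string",
      "format": "uri",
      "description": "URI of the governing schema document"
    },
    "schemaVersion": {
      "type": "integer",
      "minimum": 1,
      "description": "version of the record model"
    },
    "genome": {
      "type": "string",
      "description": "name of the genome (human-readable name, ID, or URI)"
    },
    "taxon": {
      "type": "object",
      "required": ["name", "uri"],
      "properties": {
        "name": { "type": "string" },
        "uri": {
          "type": "string",
          "format": "uri",
          "description": "taxonomy URI hosted at identifiers.org or bioregistry.io"
        }
      },
      "description": "taxonomic identification of the genome"
    },
    "version": {
      "type": "string",
      "description": "version of the genome assembly (free text)"
    },
    "assemblyAuthor": {
      "type": "array",
      "minItems": 1,
      "items": { "$ref": "#/$defs/agent" },
      "description": "assembler(s) of the genome"
    },
    "metadataAuthor": {
      "type": "array",
      "minItems": 1,
      "items": { "$ref": "#/$defs/agent" },
      "description": "author(s) of this metadata record"
    },
    "dateCreated": {
      "type": "string",
      "pattern": "^[0-9]{4}-[0-9]{2}-[0-9]{2}$",
      "description": "ISO-8601 calendar date the assembly was created"
    },
    "checksum": {
      "type": "string",
      "pattern": "^(md5|sha1|sha256):[0-9a-f]+$",
      "description": "self-referential digest over sequences plus header, excluding this field"
    },
    "accessionID": {
      "type": "object",
      "required": ["name"],
      "properties": {
        "name": { "type": "string" },
        "uri": { "type": "string", "format": "uri" }
      },
      "description": "physical ID of the genome assembly"
    },
    "assemblySoftware": {
      "type": "string",
      "description": "assembly software used in the creation of the genome"
    },
    "documentation": {
      "type": "string",
      "description": "free-text documentation about the genome"
    },
    "funding": {
      "type": "array",
      "items": { "type": "string" },
      "description": "grant line items"
    },
    "genomeSynonym": {
      "type": "array",
      "items": { "type": "string" },
      "description": "other names of the genome"
    },
    "identifier": {
      "type": "array",
      "items": { "type": "string", "pattern": "^[A-Za-z0-9._-]+:\\S+$" },
      "description": "CURIEs identifying the genome"
    },
    "instrument": {
      "type": "array",
      "items": { "type": "string" },
      "description": "sequencing and preparation instruments used"
    },
    "reuseConditions": {
      "type": "string",
      "description": "licensing terms for the genomic data"
    },
    "relatedLink": {
      "type": "array",
      "items": { "type": "string", "format": "uri" },
      "description": "URLs related to the genome (host site, mirrors)"
    },
    "scholarlyArticle": {
      "type": "array",
      "items": { "type": "string", "format": "uri" },
      "description": "publication(s) describing the genome"
    },
    "voucherSpecimen": {
      "type": "string",
      "description": "location of the sequenced physical material"
    }
  },
  "$defs": {
    "agent": {
      "type": "object",
      "required": ["name"],
      "properties": {
        "name": { "type": "string" },
        "uri": { "type": "string", "format": "uri" }
      }
    }
  }
}
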